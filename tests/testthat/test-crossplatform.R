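test_that("membership patterns match hand enumeration", {
  ov <- overlap_analysis(list(A = c("1", "2", "3"), B = c("2", "3", "4"),
                              C = "3"))
  expect_equal(ov$union_size, 4L)
  expect_equal(unname(ov$membership_counts[c("A", "A+B", "A+B+C", "B")]),
               c(1L, 1L, 1L, 1L))
  expect_equal(sum(ov$membership_counts), ov$union_size)
  expect_equal(unname(ov$k_way_counts), c(4L, 2L, 1L))
})

test_that("degenerate overlap cases behave", {
  same <- overlap_analysis(list(X = c("a", "b"), Y = c("b", "a")))
  expect_equal(unname(same$membership_counts["X+Y"]), 2L)
  expect_length(same$membership_counts, 1L)

  disj <- overlap_analysis(list(X = c("a", "b"), Y = c("c"), Z = c("d", "e")))
  expect_equal(disj$union_size, 5L)
  expect_setequal(names(disj$membership_counts), c("X", "Y", "Z"))
  expect_equal(unname(disj$k_way_counts), c(5L, 0L, 0L))

  # ids are harmonized case-insensitively with trimming
  harm <- overlap_analysis(list(A = "hsa-miR-21-5p ", B = "HSA-MIR-21-5P"))
  expect_equal(harm$union_size, 1L)
  expect_equal(unname(harm$membership_counts["A+B"]), 1L)

  expect_error(overlap_analysis(list(A = "x")), ">= 2")
})

test_that("pattern counts equal brute-force per-id enumeration", {
  withr::with_seed(88, {
    for (trial in 1:40) {
      n_plat <- sample(2:6, 1)
      ids <- sprintf("mir-%03d", 1:200)
      sets <- lapply(seq_len(n_plat), function(i)
        sample(ids, sample(0:150, 1)))
      names(sets) <- LETTERS[seq_len(n_plat)]
      ov <- overlap_analysis(sets)
      # brute force: per id, find its exact membership
      union_ids <- unique(unlist(sets))
      brute <- table(vapply(union_ids, function(id) {
        paste(names(sets)[vapply(sets, function(s) id %in% s, NA)],
              collapse = "+")
      }, ""))
      expect_equal(ov$union_size, length(union_ids))
      expect_equal(ov$membership_counts[order(names(ov$membership_counts))],
                   stats::setNames(as.integer(brute), names(brute))[
                     order(names(brute))])
      for (k in seq_len(n_plat)) {
        expect_equal(unname(ov$k_way_counts[k]),
                     sum(vapply(union_ids, function(id)
                       sum(vapply(sets, function(s) id %in% s, NA)), 0) >= k))
      }
    }
  })
})

test_that("panel accounting splits discrepancies by panel membership", {
  acc <- panel_accounting(
    sets = list(A = c("x", "y"), B = character(0)),
    panels = list(A = c("x", "y", "z"), B = "x"))
  row <- acc[acc$platform_a == "A" & acc$platform_b == "B", ]
  expect_equal(row$detected_by_a_not_b, 2L)
  expect_equal(row$absent_from_b_panel, 1L)      # y is not on B's panel
  expect_equal(row$present_but_undetected, 1L)   # x is, but B missed it
  expect_equal(row$frac_absent, 0.5)

  ident <- panel_accounting(sets = list(A = "x", B = "x"),
                            panels = list(A = c("x", "y"), B = c("x", "y")))
  expect_true(all(ident$detected_by_a_not_b == 0L))

  expect_error(panel_accounting(sets = list(A = "q", B = "x"),
                                panels = list(A = "x", B = "x")),
               "outside its own panel")
})

test_that("panel accounting is consistent with pairwise overlap differences", {
  withr::with_seed(89, {
    ids <- sprintf("m-%02d", 1:60)
    sets <- list(P1 = sample(ids, 30), P2 = sample(ids, 20),
                 P3 = sample(ids, 40))
    panels <- list(P1 = ids, P2 = ids, P3 = ids)
    acc <- panel_accounting(sets, panels)
    for (i in seq_len(nrow(acc))) {
      a <- acc$platform_a[i]; b <- acc$platform_b[i]
      expect_equal(acc$detected_by_a_not_b[i],
                   length(setdiff(tolower(sets[[a]]), tolower(sets[[b]]))))
      expect_equal(acc$absent_from_b_panel[i] + acc$present_but_undetected[i],
                   acc$detected_by_a_not_b[i])
    }
  })
})

test_that("the comparison report aggregates components and flags exclusions", {
  truth <- simulate_truth(300, seed = 91)
  m <- simulate_seq_runs(truth, seq_noise_model(depth = 4e5, rho = 0,
                                                mirna_fraction = 0.5),
                         n_runs = 4, seed = 92)
  spec <- platform_spec("seqA", "sequencing", truth$mirna_ids,
                        list(min_reads = 5), "counts")
  rs <- run_set(m, spec, "ref")
  ll <- lloq_pipeline(m, min_runs = 3)
  cc <- pairwise_run_concordance(rpm_normalize(m))
  rep1 <- comparison_report(list(seqA = rs), list(seqA = ll), list(seqA = cc))
  row <- rep1$table
  expect_equal(row$panel_size, 300L)
  expect_equal(row$average_ccc, cc$average_ccc)
  expect_equal(row$n_above_lloq, length(ll$above_lloq))
  expect_equal(row$lloq_value, ll$lloq_value)
  med <- stats::median(ll$stats$cv[ll$stats$mirna_id %in% ll$above_lloq]) * 100
  expect_equal(row$median_pct_cv_above_lloq, med)

  # a platform whose trend never dips below the cutoff is excluded with a note
  ll_bad <- ll
  ll_bad$boundary_flag <- "all_above_cutoff"
  ll_bad$lloq_value <- NA_real_
  rep2 <- comparison_report(list(seqA = rs), list(seqA = ll_bad),
                            list(seqA = cc))
  expect_equal(rep2$table$n_above_lloq, 0L)
  expect_match(rep2$notes, "could not be calculated", all = FALSE)

  # missing components leave gaps and count warnings
  rep3 <- comparison_report(list(seqA = rs))
  expect_true(is.na(rep3$table$average_ccc))
  expect_equal(rep3$n_warnings, 2L)

  # regeneration is byte-identical
  expect_identical(format_comparison_report(rep1),
                   format_comparison_report(
                     comparison_report(list(seqA = rs), list(seqA = ll),
                                       list(seqA = cc))))
})
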