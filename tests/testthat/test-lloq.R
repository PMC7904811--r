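test_that("replicate statistics use the n-1 denominator and detection gate", {
  m <- counts_mat(100, 100, 100,
                  1, 2, 3,
                  5, NA, 9, nrow = 3, scale = "rpm",
                  ids = c("flat", "spread", "gappy"))
  st <- compute_replicate_stats(m, min_runs = 3)
  expect_equal(st$mean_expression[st$mirna_id == "flat"], 100)
  expect_equal(st$cv[st$mirna_id == "flat"], 0)
  expect_equal(st$mean_expression[st$mirna_id == "spread"], 2)
  expect_equal(st$sd_expression[st$mirna_id == "spread"], 1)
  expect_equal(st$cv[st$mirna_id == "spread"], 0.5)
  expect_true(is.na(st$cv[st$mirna_id == "gappy"]))   # 2 of 3 runs detected
  expect_equal(st$n_detected[st$mirna_id == "gappy"], 2)
  expect_error(compute_replicate_stats(counts_mat(1, 2, nrow = 1,
                                                  runs = c("a", "b"),
                                                  scale = "rpm")),
               "min_runs")
})

test_that("linearize maps Ct to relative abundance and keeps masks", {
  m <- counts_mat(40, 30, NA, 20, nrow = 2, scale = "ct",
                  ids = c("a", "b"))
  lin <- linearize(m)
  expect_equal(unname(unclass(lin)["a", ]), c(1, 1024))
  expect_true(is.na(unclass(lin)["b", 1]))
  expect_identical(expr_scale(lin), "normalized_counts")

  curve <- fit_standard_curve(10^(2:7), 41 - 3 * log10(10^(2:7)))
  lin2 <- linearize(m, curves = list(a = curve, b = curve))
  expect_equal(unclass(lin2)["a", 2], ct_to_copies(curve, 30)$copies)
  expect_identical(expr_scale(lin2), "copies")
  expect_error(linearize(m, curves = list(a = curve)), "b")
})

test_that("LOESS trend reproduces smooth targets", {
  # constant CV
  st_const <- structure(data.frame(
    mirna_id = sprintf("m%03d", 1:100),
    mean_expression = 10^seq(0, 4, length.out = 100),
    sd_expression = NA_real_, cv = 0.3, n_detected = 3L),
    class = c("replicate_stats", "data.frame"))
  tr <- fit_cv_trend(st_const)
  expect_true(all(abs(tr$fitted_cv - 0.3) < 0.01))
  expect_true(all(diff(tr$grid) > 0))

  # cv = 1/sqrt(mean) on 500 log-spaced miRNAs
  means <- 10^seq(0, 5, length.out = 500)
  st_root <- structure(data.frame(
    mirna_id = sprintf("m%03d", 1:500), mean_expression = means,
    sd_expression = NA_real_, cv = 1 / sqrt(means), n_detected = 3L),
    class = c("replicate_stats", "data.frame"))
  # the 1/sqrt target curves strongly on the log abscissa; a local fit
  # tracking it to 5% needs a narrow window
  tr2 <- fit_cv_trend(st_root, span = 0.2)
  interior <- tr2$grid >= quantile(tr2$grid, 0.1) &
    tr2$grid <= quantile(tr2$grid, 0.9)
  target <- 1 / sqrt(10^tr2$grid[interior])
  expect_true(all(abs(tr2$fitted_cv[interior] - target) <= 0.05 * target + 5e-4))

  expect_error(fit_cv_trend(st_const[1:10, ]), "20")
})

test_that("larger spans smooth more (smaller total variation)", {
  st <- withr::with_seed(31, {
    means <- 10^runif(300, 0, 4)
    structure(data.frame(
      mirna_id = sprintf("m%03d", 1:300), mean_expression = means,
      sd_expression = NA_real_,
      cv = pmax(1 / sqrt(means) + rnorm(300, 0, 0.1), 0.01),
      n_detected = 3L), class = c("replicate_stats", "data.frame"))
  })
  tv <- function(span) sum(abs(diff(fit_cv_trend(st, span = span)$fitted_cv)))
  expect_lt(tv(1.0), tv(0.3))
})

test_that("LLOQ crossing is interpolated at the highest downward crossing", {
  mk_trend <- function(grid, cv) structure(list(grid = grid, fitted_cv = cv,
                                                span = 0.75,
                                                n_points = length(grid)),
                                           class = "cv_trend")
  # simple linear descent: crosses 0.5 exactly halfway between 1 and 2
  tr <- mk_trend(c(0, 1, 2, 3), c(0.9, 0.7, 0.3, 0.1))
  ll <- estimate_lloq(tr)
  expect_identical(ll$boundary_flag, "interior_crossing")
  expect_equal(log10(ll$lloq_value), 1.5)

  # non-monotone: later re-ascent above cutoff, take the highest descent
  tr2 <- mk_trend(0:5, c(0.9, 0.4, 0.6, 0.55, 0.45, 0.2))
  ll2 <- estimate_lloq(tr2)
  expect_gt(log10(ll2$lloq_value), 3)
  expect_lt(log10(ll2$lloq_value), 4)

  low <- estimate_lloq(mk_trend(0:3, rep(0.2, 4)))
  expect_identical(low$boundary_flag, "all_below_cutoff")
  expect_equal(low$lloq_value, 1)    # grid minimum, 10^0

  high <- estimate_lloq(mk_trend(0:3, rep(0.8, 4)))
  expect_identical(high$boundary_flag, "all_above_cutoff")
  expect_true(is.na(high$lloq_value))
})

test_that("classification is boundary-inclusive and flag-aware", {
  st <- structure(data.frame(
    mirna_id = c("lo", "mid", "hi", "undef"),
    mean_expression = c(2, 4, 8, 100), sd_expression = NA_real_,
    cv = c(0.6, 0.4, 0.2, NA), n_detected = c(3L, 3L, 3L, 1L)),
    class = c("replicate_stats", "data.frame"))
  mk <- function(flag, v) structure(list(lloq_value = v, cutoff = 0.5,
                                         boundary_flag = flag),
                                    class = "lloq_result")
  expect_equal(classify_above_lloq(st, mk("interior_crossing", 4)),
               c("mid", "hi"))
  expect_equal(classify_above_lloq(st, mk("all_above_cutoff", NA)), character(0))
  # all_below_cutoff with lloq at the observed minimum: every defined CV passes
  expect_setequal(classify_above_lloq(st, mk("all_below_cutoff", 2)),
                  c("lo", "mid", "hi"))
})

test_that("serum-preset LLOQ recovery brackets the analytic crossing", {
  # compositional noise rho = 0.125: CV^2 = 1/mu + rho crosses 0.25 at
  # mu = 8 reads; every seed must land within 2x of it
  pre <- simulation_preset("serum")
  lloqs <- vapply(1:20, function(s) {
    truth <- do.call(simulate_truth, c(pre$truth_params, list(seed = 7000 + s)))
    runs <- simulate_seq_runs(truth, pre$seq_model, n_runs = 4, seed = s)
    lloq_pipeline(runs, min_runs = 3)$lloq_value
  }, 0)
  expect_lte(abs(stats::median(lloqs) - 8) / 8, 0.30)
  expect_true(all(lloqs >= 4 & lloqs <= 16))
})

test_that("the quantifiable set grows with a looser CV cutoff", {
  runs <- sim_small_seq(51, rho = 0.125, n_mirnas = 600, depth = 4e5)
  st <- compute_replicate_stats(runs, min_runs = 3)
  tr <- fit_cv_trend(st)
  sizes <- vapply(c(0.3, 0.5, 0.7), function(cut)
    length(classify_above_lloq(st, estimate_lloq(tr, cutoff = cut))), 0L)
  expect_true(all(diff(sizes) >= 0))
})

test_that("LLOQ scales exactly with a global expression rescaling", {
  runs <- sim_small_seq(52, rho = 0, n_mirnas = 400)
  rpm <- rpm_normalize(runs)
  ll1 <- lloq_pipeline(rpm, min_runs = 3)
  scaled <- expr_matrix(unclass(rpm) * 37, "normalized_counts")
  ll2 <- lloq_pipeline(scaled, min_runs = 3)
  expect_equal(ll2$lloq_value, 37 * ll1$lloq_value, tolerance = 1e-6)
})

test_that("the CV trend is invariant to miRNA ordering", {
  runs <- sim_small_seq(53, rho = 0, n_mirnas = 300)
  st <- compute_replicate_stats(runs, min_runs = 3)
  perm <- withr::with_seed(9, sample(nrow(st)))
  st_perm <- st[perm, ]
  class(st_perm) <- class(st)
  tr1 <- fit_cv_trend(st)
  tr2 <- fit_cv_trend(st_perm)
  expect_equal(tr2$fitted_cv, tr1$fitted_cv, tolerance = 1e-10)
})
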