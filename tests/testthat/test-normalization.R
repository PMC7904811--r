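test_that("standard curves recover an exact dilution line", {
  copies <- 10^(2:7)
  fit <- fit_standard_curve(copies, 41 - 3 * log10(copies))
  expect_equal(fit$slope, -3, tolerance = 1e-12)
  expect_equal(fit$intercept, 41, tolerance = 1e-12)
  expect_equal(fit$fit_r2, 1, tolerance = 1e-12)
  expect_equal(fit$dilution_range, c(1e2, 1e7))

  expect_error(fit_standard_curve(c(100, 1000), c(35, 32)), ">= 3")
  expect_error(fit_standard_curve(rep(1000, 6), rep(31, 6)), "degenerate")
})

test_that("noisy dilution series estimate the slope within OLS error", {
  copies <- 10^(2:7)
  hits <- withr::with_seed(42, {
    vapply(1:200, function(i) {
      cts <- 41 - 3.32 * log10(copies) + stats::rnorm(6, 0, 0.1)
      abs(fit_standard_curve(copies, cts)$slope + 3.32) <= 0.15
    }, NA)
  })
  expect_gte(mean(hits), 0.95)
})

test_that("ct_to_copies inverts the line and flags extrapolation", {
  curve <- fit_standard_curve(10^(2:7), 41 - 3 * log10(10^(2:7)))
  at20 <- ct_to_copies(curve, 20)
  expect_equal(at20$copies, 1e7, tolerance = 1e-9)
  expect_false(at20$extrapolated)

  at_intercept <- ct_to_copies(curve, 41)
  expect_equal(at_intercept$copies, 1, tolerance = 1e-12)
  expect_true(at_intercept$extrapolated)   # below the 10^2 series floor

  # round-trip through a noisy fit is the identity on the fitted line
  cts <- withr::with_seed(1, 40 - 3.1 * log10(10^(2:7)) + stats::rnorm(6, 0, 0.2))
  fit <- fit_standard_curve(10^(2:7), cts)
  on_line <- fit$intercept + fit$slope * log10(12345)
  expect_equal(ct_to_copies(fit, on_line)$copies, 12345, tolerance = 1e-9)
})

test_that("copies scale to biofluid concentration by volume arithmetic", {
  expect_equal(copies_to_concentration(1000, 1 / 15, 0.2), 75000)
  expect_equal(copies_to_concentration(1234, 1, 1), 1234)
  expect_equal(copies_to_concentration(1000, 1 / 15, 0.4),
               copies_to_concentration(1000, 1 / 15, 0.2) / 2)
  expect_error(copies_to_concentration(10, 0, 1), "rt_input_fraction")
})

test_that("residual-Ct spike-in normalization matches the hand rule", {
  m <- counts_mat(20, 21, 22,
                  30, 30, 30,
                  25, 26, 24, nrow = 3, scale = "ct",
                  ids = c("spike", "tgt1", "tgt2"))
  out <- spikein_normalize_ct(m, spike_in_set("spike"))
  # spike reads 20,21,22 (mean 21): run1 factor = -1 so Ct 30 -> 31
  expect_equal(unname(out["tgt1", ]), c(31, 30, 29))
  expect_false("spike" %in% mirna_ids(out))

  # identical runs: factors vanish, output = input minus spike rows
  m0 <- counts_mat(20, 20, 31, 31, nrow = 2, scale = "ct",
                   ids = c("spike", "tgt"))
  out0 <- spikein_normalize_ct(m0, "spike")
  expect_equal(unname(out0["tgt", ]), c(31, 31))

  # a constant plate shift in one of k runs is removed up to the c/k
  # re-centering remainder (here 3/3 = 1)
  shifted <- unclass(m); shifted[, 2] <- shifted[, 2] + 3
  out_s <- spikein_normalize_ct(expr_matrix(shifted, "ct"), "spike")
  expect_equal(unclass(out_s)[, 2], unclass(out)[, 2] + 1)
  # and the across-run spread the shift caused is gone: run deltas between
  # endogenous targets are preserved exactly
  expect_equal(unclass(out_s)["tgt1", ] - unclass(out_s)["tgt2", ],
               unclass(out)["tgt1", ] - unclass(out)["tgt2", ])

  masked <- unclass(m); masked["spike", 2] <- NA
  expect_error(spikein_normalize_ct(expr_matrix(masked, "ct"), "spike"),
               "spike.*run2")
})

test_that("spike residuals sum to zero across runs", {
  # a shadow endogenous row duplicating the single spike keeps its raw
  # across-run mean after normalization (the residuals average out)
  v <- withr::with_seed(4, {
    x <- matrix(stats::runif(25, 15, 35), 5, 5,
                dimnames = list(c("spike", "shadow", "t1", "t2", "t3"),
                                sprintf("run%d", 1:5)))
    x["shadow", ] <- x["spike", ]
    x
  })
  out <- spikein_normalize_ct(expr_matrix(v, "ct"), "spike")
  expect_equal(mean(unclass(out)["shadow", ]), mean(v["spike", ]),
               tolerance = 1e-12)
})

test_that("three-step hybridization normalization follows the geomean rules", {
  # negatives (1,2,4): geometric mean 2, so a raw 10 becomes 8 pre-scaling
  ids <- c(sprintf("m%02d", 1:3), sprintf("NEG%d", 1:3), "POS1")
  v <- matrix(c(10, 10,
                50, 50,
                200, 200,
                1, 1,
                2, 2,
                4, 4,
                100, 100), ncol = 2, byrow = TRUE,
              dimnames = list(ids, c("r1", "r2")))
  out <- nanostring_normalize(expr_matrix(v, "counts"),
                              neg_ids = sprintf("NEG%d", 1:3),
                              pos_ids = "POS1", top_n = 3)
  # identical runs: both scaling factors are 1, output = clamped subtraction
  expect_equal(unname(unclass(out)[, 1]), c(8, 48, 198))
  expect_identical(expr_scale(out), "normalized_counts")
  expect_false(any(grepl("NEG|POS", mirna_ids(out))))

  # single-run input: averages are over one run, so scaling is the identity
  single <- nanostring_normalize(expr_matrix(v[, 1, drop = FALSE], "counts"),
                                 sprintf("NEG%d", 1:3), "POS1", top_n = 3)
  expect_equal(unname(unclass(single)[, 1]), c(8, 48, 198))
})

test_that("with zero background the normalization cancels per-run scaling", {
  ids <- c(sprintf("m%02d", 1:6), "NEG1", "POS1")
  base <- c(5, 20, 80, 320, 1280, 5120)
  v <- cbind(r1 = c(base, 0, 400), r2 = c(base * 7, 0, 2800))
  rownames(v) <- ids
  out <- nanostring_normalize(expr_matrix(v, "counts"), "NEG1", "POS1",
                              top_n = 4)
  expect_equal(unclass(out)[, 1], unclass(out)[, 2], tolerance = 1e-12)

  pos_zero <- v; pos_zero["POS1", ] <- 0
  expect_error(nanostring_normalize(expr_matrix(pos_zero, "counts"),
                                    "NEG1", "POS1", 4), "positive-control")
})

test_that("RPM normalization is exact per-run scaling", {
  m <- counts_mat(10, 90, nrow = 2, runs = "r1")
  out <- rpm_normalize(m)
  expect_equal(unname(unclass(out)[, 1]), c(1e5, 9e5))

  big <- sim_small_seq(21)
  rpm <- rpm_normalize(big)
  expect_equal(unname(colSums(unclass(rpm), na.rm = TRUE)),
               rep(1e6, ncol(rpm)), tolerance = 1e-9)

  perm <- withr::with_seed(5, sample(nrow(big)))
  rpm_perm <- rpm_normalize(expr_matrix(unclass(big)[perm, ], "counts"))
  expect_equal(unclass(rpm_perm), unclass(rpm)[perm, ], ignore_attr = TRUE)

  zero <- counts_mat(0, 1, 0, 2, nrow = 2, runs = c("bad", "ok"))
  expect_error(rpm_normalize(zero), "bad")
})
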