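#' Lin's concordance correlation coefficient
#'
#' The closed form
#' `ccc = 2 * s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)`,
#' with population (n-denominator) variance and covariance terms, as in
#' Lin (1989). The coefficient penalizes both scatter about the best-fit
#' line and location/scale departure from the identity line, so
#' `|ccc| <= |Pearson r|` with equality only when means and variances
#' match. The n denominator (rather than n - 1) is a documented choice:
#' at small n the two differ slightly.
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant
#' @return the concordance correlation coefficient, in \[-1, 1\]
#' @examples
#' lin_ccc(c(1, 2, 3), c(2, 3, 4))  # 4/7
#' @export
lin_ccc <- function(x, y) {
  if (length(x) != length(y)) stop_mirplat("x and y must have equal length")
  if (length(x) < 3L) stop_mirplat("need at least 3 paired observations")
  if (anyNA(x) || anyNA(y)) stop_mirplat("missing values are not allowed")
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sx2 <- sum((x - mx)^2) / n
  sy2 <- sum((y - my)^2) / n
  if (sx2 == 0 || sy2 == 0)
    stop_mirplat("concordance is undefined for a constant vector")
  sxy <- sum((x - mx) * (y - my)) / n
  2 * sxy / (sx2 + sy2 + (mx - my)^2)
}

#' Pairwise inter-run concordance
#'
#' For every pair of runs, restricts to miRNAs detected in both, applies
#' an optional log10 transform (recommended on linear scales, where raw
#' values span several decades and a handful of abundant miRNAs would
#' otherwise dominate; Ct values are already log-scale and are used
#' directly), and computes [lin_ccc()]. The platform reproducibility
#' summary is the average of the defined upper-triangle entries; pairs
#' with fewer than 3 common miRNAs, or with a constant vector, are
#' reported as `NA` and excluded from the average with a warning.
#'
#' @param matrix an [expr_matrix()] with >= 2 runs
#' @param log_transform log10-transform values before ccc (default TRUE
#'   on linear scales; ignored for Ct matrices). Non-positive values are
#'   dropped from a pair when log-transforming.
#' @return a `concordance_result`: list with `pair_matrix` (symmetric,
#'   unit diagonal), `average_ccc`, `n_common` (pairwise counts used)
#' @export
pairwise_run_concordance <- function(matrix, log_transform = TRUE) {
  if (!inherits(matrix, "expr_matrix")) stop_mirplat("'matrix' must be an expr_matrix")
  if (ncol(matrix) < 2L) stop_mirplat("need at least 2 runs")
  vals <- unclass(matrix)
  use_log <- isTRUE(log_transform) && expr_scale(matrix) != "ct"
  k <- ncol(vals)
  pair <- matrix(NA_real_, k, k, dimnames = list(colnames(vals), colnames(vals)))
  ncom <- matrix(0L, k, k, dimnames = dimnames(pair))
  diag(pair) <- 1
  excluded <- 0L
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      xi <- vals[, i]; xj <- vals[, j]
      keep <- !is.na(xi) & !is.na(xj)
      if (use_log) keep <- keep & xi > 0 & xj > 0
      ncom[i, j] <- ncom[j, i] <- sum(keep)
      cc <- NA_real_
      if (sum(keep) >= 3L) {
        xi2 <- xi[keep]; xj2 <- xj[keep]
        if (use_log) { xi2 <- log10(xi2); xj2 <- log10(xj2) }
        cc <- tryCatch(lin_ccc(xi2, xj2), error = function(e) NA_real_)
      }
      if (is.na(cc)) excluded <- excluded + 1L
      pair[i, j] <- pair[j, i] <- cc
    }
  }
  up <- pair[upper.tri(pair)]
  if (excluded > 0L)
    warning(sprintf("ccc undefined for %d run pair(s); excluded from the average",
                    excluded), call. = FALSE)
  structure(list(pair_matrix = pair,
                 average_ccc = if (all(is.na(up))) NA_real_ else mean(up, na.rm = TRUE),
                 n_common = ncom),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("concordance_result: %d runs, average pairwise ccc = %s\n",
              nrow(x$pair_matrix),
              ifelse(is.na(x$average_ccc), "NA", sprintf("%.3f", x$average_ccc))))
  invisible(x)
}

#' Spearman correlation between two platforms
#'
#' Rank correlation of per-miRNA summary expression (typically across-run
#' means) between two platforms over their common miRNAs, with
#' average-rank tie handling and a two-sided p-value from the
#' t approximation. Because lower Ct means higher abundance, a
#' Ct-scaled input has its orientation reversed before ranking, so a
#' positive rho always means the platforms agree.
#'
#' @param a,b named numeric vectors of per-miRNA summaries
#' @param a_scale,b_scale scales of the summaries (`"ct"` triggers
#'   orientation reversal)
#' @param common_ids miRNA ids to compare; defaults to the intersection
#'   of the names of `a` and `b` (>= 3 required)
#' @return list with `rho`, `p_value`, `n`
#' @export
spearman_platform_correlation <- function(a, b, a_scale = "counts",
                                          b_scale = "counts",
                                          common_ids = NULL) {
  if (is.null(common_ids)) common_ids <- intersect(names(a), names(b))
  common_ids <- as.character(common_ids)
  missing_ids <- setdiff(common_ids, intersect(names(a), names(b)))
  if (length(missing_ids) > 0L)
    stop_mirplat("id(s) absent from a summary: %s",
                 paste(utils::head(missing_ids, 3), collapse = ", "))
  x <- unname(a[common_ids]); y <- unname(b[common_ids])
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop_mirplat("need >= 3 common miRNAs with values")
  if (identical(a_scale, "ct")) x <- -x
  if (identical(b_scale, "ct")) y <- -y
  ht <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ht$estimate), p_value = ht$p.value, n = length(x))
}
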