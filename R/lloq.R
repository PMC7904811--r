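#' Per-miRNA replicate statistics
#'
#' Across the run columns of a linear-scale matrix, computes for each
#' miRNA the mean, standard deviation (n - 1 denominator) and coefficient
#' of variation `cv = sd / mean` over its unmasked values. The CV is the
#' replicate-precision statistic that the LLOQ procedure smooths against
#' abundance. A miRNA's CV is defined only when it is detected in at
#' least `min_runs` runs and its mean is positive; otherwise `cv` is
#' `NA`. At three or four replicate runs the n - 1 denominator is a
#' material choice (the alternative n denominator shrinks every CV by
#' `sqrt((n-1)/n)`).
#'
#' @param matrix an [expr_matrix()] on a linear scale (`counts`, `copies`,
#'   `copies_per_ml`, `rpm` or `normalized_counts`); Ct data must first be
#'   passed through [linearize()]
#' @param min_runs minimal number of detected runs for a defined CV
#'   (default 3, mirroring the at-least-three-independent-runs design)
#' @return a `replicate_stats` data.frame: `mirna_id`, `mean_expression`,
#'   `sd_expression`, `cv`, `n_detected`, with a `scale` attribute
#' @export
compute_replicate_stats <- function(matrix, min_runs = 3L) {
  if (!inherits(matrix, "expr_matrix")) stop_mirplat("'matrix' must be an expr_matrix")
  if (expr_scale(matrix) == "ct")
    stop_mirplat("CV statistics need a linear scale; use linearize() on Ct data")
  if (ncol(matrix) < min_runs)
    stop_mirplat("matrix has %d runs but min_runs = %d", ncol(matrix), min_runs)
  vals <- unclass(matrix)
  n_det <- rowSums(!is.na(vals))
  m <- rowMeans(vals, na.rm = TRUE)
  s <- apply(vals, 1L, stats::sd, na.rm = TRUE)
  m[n_det == 0L] <- NA_real_
  cv <- ifelse(n_det >= min_runs & !is.na(m) & m > 0, s / m, NA_real_)
  out <- data.frame(mirna_id = rownames(vals), mean_expression = unname(m),
                    sd_expression = unname(s), cv = unname(cv),
                    n_detected = unname(n_det), stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "scale") <- expr_scale(matrix)
  class(out) <- c("replicate_stats", "data.frame")
  out
}

#' Linearize a Ct matrix
#'
#' Converts threshold cycles to a linear abundance scale so that CVs are
#' comparable with count-based platforms. With per-miRNA standard curves
#' the conversion is absolute ([ct_to_copies()]); without curves it is
#' the relative transform `2^(ct_ref - ct)` (100% amplification
#' efficiency assumed), anchored so that `ct = ct_ref` maps to 1.
#' Masked cells stay masked.
#'
#' @param matrix a ct-scaled [expr_matrix()]
#' @param curves optional named list of [fit_standard_curve()] objects,
#'   one per miRNA row; an error is raised if any row lacks a curve
#' @param ct_ref reference Ct for the relative transform (default 40)
#' @return an [expr_matrix()] on the `copies` scale (with curves) or
#'   `normalized_counts` scale (relative transform)
#' @export
linearize <- function(matrix, curves = NULL, ct_ref = 40) {
  if (!inherits(matrix, "expr_matrix") || expr_scale(matrix) != "ct")
    stop_mirplat("'matrix' must be a ct-scaled expr_matrix")
  vals <- unclass(matrix)
  if (is.null(curves)) {
    return(expr_matrix(2^(ct_ref - vals), scale = "normalized_counts"))
  }
  missing_curves <- setdiff(rownames(vals), names(curves))
  if (length(missing_curves) > 0L)
    stop_mirplat("no standard curve for miRNA(s): %s",
                 paste(utils::head(missing_curves, 3), collapse = ", "))
  out <- vals
  for (id in rownames(vals))
    out[id, ] <- ct_to_copies(curves[[id]], vals[id, ])$copies
  expr_matrix(out, scale = "copies")
}

#' LOESS trend of replicate CV against abundance
#'
#' Fits a degree-1 LOESS (tricube weights, no robustness iterations) of
#' CV on log10(mean expression) over all miRNAs with a defined CV, and
#' evaluates the smooth on a 200-point grid spanning the observed
#' abundance range. This is the empirical precision profile whose 50%-CV
#' crossing defines the LLOQ.
#'
#' @param stats a [compute_replicate_stats()] result with at least 20
#'   defined CVs (fewer points make the local fit unstable; pool more
#'   runs or miRNAs)
#' @param span LOESS span (default 0.75)
#' @param n_grid number of grid points (default 200)
#' @return a `cv_trend`: list with `grid` (log10 mean expression,
#'   strictly increasing), `fitted_cv`, `span`, `n_points`
#' @export
fit_cv_trend <- function(stats, span = 0.75, n_grid = 200L) {
  if (!inherits(stats, "replicate_stats"))
    stop_mirplat("'stats' must come from compute_replicate_stats()")
  ok <- !is.na(stats$cv) & stats$mean_expression > 0
  if (sum(ok) < 20L)
    stop_mirplat("only %d miRNAs with defined CV (< 20); pool more runs or miRNAs",
                 sum(ok))
  lx <- log10(stats$mean_expression[ok])
  cv <- stats$cv[ok]
  o <- order(lx)
  fit <- stats::loess(cv ~ lx, data = data.frame(lx = lx[o], cv = cv[o]),
                      span = span, degree = 1, family = "gaussian",
                      surface = "direct",
                      control = stats::loess.control(statistics = "none"))
  grid <- seq(min(lx), max(lx), length.out = n_grid)
  fitted_cv <- as.numeric(stats::predict(fit, newdata = data.frame(lx = grid)))
  if (any(!is.finite(fitted_cv)))
    stop_mirplat("LOESS produced non-finite trend values; check input CVs")
  structure(list(grid = grid, fitted_cv = fitted_cv, span = span,
                 n_points = sum(ok)), class = "cv_trend")
}

#' Estimate the LLOQ from a CV trend
#'
#' The lower limit of quantification is the expression level at which
#' the smoothed CV trend crosses the cutoff (50% CV by default) from
#' above. When the LOESS trend is non-monotone there may be several
#' crossings; the highest (largest-abundance) downward crossing is
#' taken, the conservative choice that guarantees the fitted CV stays at
#' or below the cutoff for every abundance above the LLOQ. The crossing
#' abscissa is linearly interpolated between the bracketing grid points
#' and returned on the linear expression scale.
#'
#' Boundary cases: a trend at or below the cutoff everywhere yields the
#' grid minimum with flag `all_below_cutoff` (everything quantifiable);
#' a trend above the cutoff everywhere yields `NA` with flag
#' `all_above_cutoff` (no LLOQ can be calculated — the platform is too
#' variable across its whole observed range).
#'
#' @param trend a [fit_cv_trend()] result
#' @param cutoff CV cutoff as a fraction (default 0.5, i.e. 50% CV)
#' @return an `lloq_result`: list with `lloq_value` (linear expression
#'   units), `cutoff`, `boundary_flag` (`interior_crossing`,
#'   `all_below_cutoff` or `all_above_cutoff`) and the `trend`
#' @export
estimate_lloq <- function(trend, cutoff = 0.5) {
  stopifnot(inherits(trend, "cv_trend"))
  assert_scalar_number(cutoff, "cutoff", positive = TRUE)
  f <- trend$fitted_cv
  g <- trend$grid
  above <- f > cutoff
  if (!any(above)) {
    return(structure(list(lloq_value = 10^g[1L], cutoff = cutoff,
                          boundary_flag = "all_below_cutoff", trend = trend),
                     class = "lloq_result"))
  }
  if (all(above)) {
    return(structure(list(lloq_value = NA_real_, cutoff = cutoff,
                          boundary_flag = "all_above_cutoff", trend = trend),
                     class = "lloq_result"))
  }
  down <- which(above[-length(above)] & !above[-1L])  # > cutoff then <= cutoff
  if (length(down) == 0L) {
    # only upward crossings exist (trend rises through the cutoff); treat the
    # region above the last grid point at/below cutoff as unquantifiable
    return(structure(list(lloq_value = NA_real_, cutoff = cutoff,
                          boundary_flag = "all_above_cutoff", trend = trend),
                     class = "lloq_result"))
  }
  i <- max(down)
  x <- g[i] + (cutoff - f[i]) * (g[i + 1L] - g[i]) / (f[i + 1L] - f[i])
  structure(list(lloq_value = 10^x, cutoff = cutoff,
                 boundary_flag = "interior_crossing", trend = trend),
            class = "lloq_result")
}

#' @export
print.lloq_result <- function(x, ...) {
  cat(sprintf("lloq_result: flag = %s, cutoff = %.0f%% CV, LLOQ = %s\n",
              x$boundary_flag, 100 * x$cutoff,
              if (is.na(x$lloq_value)) "not calculable" else
                format(x$lloq_value, digits = 4)))
  invisible(x)
}

#' Classify miRNAs above the LLOQ
#'
#' A miRNA is quantifiable when its CV is defined and its mean
#' expression is at or above the LLOQ (boundary inclusive). With flag
#' `all_above_cutoff` no miRNA is quantifiable; with `all_below_cutoff`
#' every CV-defined miRNA is.
#'
#' @param stats the [compute_replicate_stats()] used to fit the trend
#' @param lloq an [estimate_lloq()] result
#' @return character vector of quantifiable miRNA ids
#' @export
classify_above_lloq <- function(stats, lloq) {
  stopifnot(inherits(stats, "replicate_stats"), inherits(lloq, "lloq_result"))
  if (lloq$boundary_flag == "all_above_cutoff") return(character(0))
  stats$mirna_id[!is.na(stats$cv) & stats$mean_expression >= lloq$lloq_value]
}

#' Full LLOQ pipeline on one replicate matrix
#'
#' Convenience wrapper: [compute_replicate_stats()] then
#' [fit_cv_trend()] then [estimate_lloq()] then
#' [classify_above_lloq()].
#'
#' @inheritParams compute_replicate_stats
#' @inheritParams fit_cv_trend
#' @inheritParams estimate_lloq
#' @return an `lloq_result` augmented with `stats` and `above_lloq`
#' @export
lloq_pipeline <- function(matrix, min_runs = 3L, span = 0.75, cutoff = 0.5) {
  stats <- compute_replicate_stats(matrix, min_runs = min_runs)
  trend <- fit_cv_trend(stats, span = span)
  res <- estimate_lloq(trend, cutoff = cutoff)
  res$stats <- stats
  res$above_lloq <- classify_above_lloq(stats, res)
  res
}
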