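#' Subsample a read-count vector without replacement
#'
#' Draws `target_total` reads from the finite pool of observed reads
#' (multivariate hypergeometric), realized as sequential conditional
#' univariate hypergeometric draws. Subsampling an already-sequenced
#' library is a finite-pool operation, hence without replacement; at
#' typical depths the result is indistinguishable from binomial
#' thinning, but the contract is fixed. The output totals exactly
#' `target_total` and no component exceeds its source.
#'
#' @param counts integer vector of observed read counts
#' @param target_total reads to draw, `0 <= target_total <= sum(counts)`
#' @param seed optional integer seed (NULL uses the current RNG stream)
#' @return integer-valued vector, same length and names as `counts`
#' @export
subsample_counts <- function(counts, target_total, seed = NULL) {
  if (any(is.na(counts)) || any(counts < 0))
    stop_mirplat("counts must be non-negative and complete")
  total <- sum(counts)
  if (target_total > total)
    stop_mirplat("target_total (%g) exceeds available reads (%g)",
                 target_total, total)
  if (target_total < 0) stop_mirplat("target_total must be >= 0")
  with_seed_or_current(seed, {
    out <- numeric(length(counts))
    need <- target_total
    remaining <- total
    for (i in seq_along(counts)) {
      if (need == 0) break
      remaining <- remaining - counts[i]
      if (remaining == 0) { out[i] <- need; need <- 0; break }
      xi <- stats::rhyper(1L, counts[i], remaining, need)
      out[i] <- xi
      need <- need - xi
    }
    names(out) <- names(counts)
    out
  })
}

#' Detection rate as a function of sequencing depth
#'
#' For each run, each depth on the grid and each resample, subsamples
#' the run's reads to that depth and counts the miRNAs at or above the
#' detection limit (`lod`, default 5 reads). Means and SDs are taken
#' over all (run, resample) combinations per depth.
#'
#' @param matrix a counts-scaled [expr_matrix()]
#' @param depth_grid increasing vector of target depths, each feasible
#'   for every run
#' @param lod detection limit in reads (default 5)
#' @param n_resamples subsample replicates per run and depth (default 20)
#' @param seed integer seed
#' @return a `subsample_curve`: list with `depth_grid`, `detected_mean`,
#'   `detected_sd`, `lod`, `n_resamples`
#' @export
detection_curve <- function(matrix, depth_grid, lod = 5L, n_resamples = 20L,
                            seed = 1L) {
  if (!inherits(matrix, "expr_matrix") || expr_scale(matrix) != "counts")
    stop_mirplat("'matrix' must be a counts-scaled expr_matrix")
  depth_grid <- sort(unique(as.numeric(depth_grid)))
  vals <- unclass(matrix)
  vals[is.na(vals)] <- 0
  totals <- colSums(vals)
  if (any(depth_grid > min(totals)))
    stop_mirplat("depth %g exceeds the smallest run total (%g)",
                 max(depth_grid), min(totals))
  detected <- with_seed_or_current(seed, {
    lapply(depth_grid, function(d) {
      as.vector(vapply(seq_len(ncol(vals)), function(r) {
        vapply(seq_len(n_resamples), function(s) {
          sum(subsample_counts(vals[, r], d) >= lod)
        }, 0)
      }, numeric(n_resamples)))
    })
  })
  structure(list(depth_grid = depth_grid,
                 detected_mean = vapply(detected, mean, 0),
                 detected_sd = vapply(detected, stats::sd, 0),
                 lod = lod, n_resamples = as.integer(n_resamples)),
            class = "subsample_curve")
}

#' LLOQ as a function of sequencing depth
#'
#' At each depth on the grid, subsamples every replicate run to that
#' depth and runs the LLOQ pipeline ([compute_replicate_stats()] ->
#' [fit_cv_trend()] -> [estimate_lloq()]) on the subsampled counts. The
#' LLOQ is reported in mapped reads per miRNA (the input unit); depths
#' where the trend never drops below the cutoff are recorded as `NA`.
#'
#' @param matrix a counts-scaled [expr_matrix()] with >= 3 replicate runs
#' @param depth_grid increasing vector of feasible depths
#' @param span LOESS span passed to [fit_cv_trend()]
#' @param cutoff CV cutoff passed to [estimate_lloq()]
#' @param min_runs detection gate passed to [compute_replicate_stats()]
#' @param seed integer seed
#' @return a `subsample_curve` list with `depth_grid`, `lloq_reads` (and
#'   the per-depth boundary flags)
#' @export
lloq_vs_depth <- function(matrix, depth_grid, span = 0.75, cutoff = 0.5,
                          min_runs = 3L, seed = 1L) {
  if (!inherits(matrix, "expr_matrix") || expr_scale(matrix) != "counts")
    stop_mirplat("'matrix' must be a counts-scaled expr_matrix")
  if (ncol(matrix) < 3L) stop_mirplat("need >= 3 replicate runs")
  depth_grid <- sort(unique(as.numeric(depth_grid)))
  vals <- unclass(matrix)
  vals[is.na(vals)] <- 0
  if (any(depth_grid > min(colSums(vals))))
    stop_mirplat("depth grid exceeds the smallest run total")
  res <- with_seed_or_current(seed, {
    lapply(depth_grid, function(d) {
      sub <- vapply(seq_len(ncol(vals)),
                    function(r) subsample_counts(vals[, r], d),
                    numeric(nrow(vals)))
      dimnames(sub) <- dimnames(vals)
      em <- expr_matrix(sub, scale = "counts")
      tryCatch({
        ll <- lloq_pipeline(em, min_runs = min_runs, span = span, cutoff = cutoff)
        list(lloq = ll$lloq_value, flag = ll$boundary_flag)
      }, error = function(e) list(lloq = NA_real_, flag = "error"))
    })
  })
  structure(list(depth_grid = depth_grid,
                 lloq_reads = vapply(res, function(x) x$lloq, 0),
                 boundary_flags = vapply(res, function(x) x$flag, ""),
                 cutoff = cutoff, span = span),
            class = "subsample_curve")
}

#' Saturation depth of a detection curve
#'
#' The smallest grid depth from which the marginal gain in detected
#' miRNAs per million additional reads stays below `gain_threshold` for
#' every later grid interval; `NA` ("not saturated") when no such depth
#' exists. A perfectly flat curve saturates at the first grid depth.
#'
#' @param curve a [detection_curve()] result (>= 3 grid points)
#' @param gain_threshold miRNAs per million additional reads (default 1)
#' @return the saturation depth, or `NA` when the curve has not
#'   saturated within the grid
#' @export
saturation_depth <- function(curve, gain_threshold = 1) {
  stopifnot(inherits(curve, "subsample_curve"))
  d <- curve$depth_grid
  y <- curve$detected_mean
  if (length(d) < 3L) stop_mirplat("need >= 3 grid points")
  gain <- diff(y) / (diff(d) / 1e6)          # gain over interval [i, i+1]
  below <- gain < gain_threshold
  stays <- rev(cumprod(rev(below))) == 1     # below here and for all later intervals
  if (!any(stays)) return(NA_real_)
  d[which(stays)[1L]]
}
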