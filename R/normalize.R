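#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Ct on log10(copies) over a synthetic-template
#' dilution series, the basis of absolute quantification by
#' intrapolation. A valid series has at least three points and spans at
#' least two decades of copy number.
#'
#' @param dilution_copies template copy numbers (strictly positive)
#' @param cts measured Ct values, same length
#' @param mirna_id optional assay identifier carried on the result
#' @return a `standard_curve`: list with `mirna_id`, `slope`, `intercept`
#'   (Ct at log10(copies) = 0, i.e. one copy), `fit_r2`, `dilution_range`
#' @examples
#' copies <- 10^(2:7)
#' fit_standard_curve(copies, 41 - 3 * log10(copies))
#' @export
fit_standard_curve <- function(dilution_copies, cts, mirna_id = NA_character_) {
  if (length(dilution_copies) != length(cts))
    stop_mirplat("dilution_copies and cts must have equal length")
  if (length(cts) < 3L) stop_mirplat("a standard curve needs >= 3 points")
  if (any(dilution_copies <= 0)) stop_mirplat("copy numbers must be positive")
  lx <- log10(dilution_copies)
  if (max(lx) - min(lx) < .Machine$double.eps^0.5)
    stop_mirplat("zero variance in log10(copies): dilution series is degenerate")
  fit <- stats::lm(cts ~ lx)
  slope <- unname(stats::coef(fit)[2L])
  if (slope >= 0)
    warning("fitted slope is non-negative; Ct should decrease with copies",
            call. = FALSE)
  ss_tot <- sum((cts - mean(cts))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else NA_real_
  structure(list(mirna_id = mirna_id,
                 slope = slope,
                 intercept = unname(stats::coef(fit)[1L]),
                 fit_r2 = r2,
                 dilution_range = range(dilution_copies)),
            class = "standard_curve")
}

#' Convert a Ct value to absolute copies via a standard curve
#'
#' Inverts the fitted line: `copies = 10^((ct - intercept) / slope)`.
#' Results outside the fitted dilution range are still returned but
#' flagged as extrapolated — the quantification is only validated by
#' intrapolation within the series.
#'
#' @param curve a [fit_standard_curve()] result
#' @param ct Ct value(s)
#' @return list with `copies` and logical `extrapolated`, both the length
#'   of `ct`
#' @export
ct_to_copies <- function(curve, ct) {
  stopifnot(inherits(curve, "standard_curve"))
  copies <- 10^((ct - curve$intercept) / curve$slope)
  # a hair of float slack so the exact series endpoints count as interior
  tol <- 1e-9
  extrapolated <- !is.na(copies) &
    (copies < curve$dilution_range[1] * (1 - tol) |
       copies > curve$dilution_range[2] * (1 + tol))
  list(copies = copies, extrapolated = extrapolated)
}

#' Scale per-reaction copies to biofluid concentration
#'
#' Converts absolute copies measured in one RT reaction to copies per ml
#' of the source biofluid: `copies / rt_input_fraction /
#' biofluid_volume_ml`, where `rt_input_fraction` is the fraction of the
#' total RNA eluate entering the reaction. The documented default
#' workflow elutes extracted RNA in 15 ul and uses 1 ul per RT reaction
#' (`rt_input_fraction = 1/15`) from 0.2 ml of serum or plasma.
#'
#' @param copies_per_reaction absolute copies in the reaction (>= 0)
#' @param rt_input_fraction fraction of the eluate in the reaction, (0, 1]
#' @param biofluid_volume_ml extracted biofluid volume in ml (> 0)
#' @return copies per ml of biofluid
#' @examples
#' copies_to_concentration(1000, rt_input_fraction = 1/15,
#'                         biofluid_volume_ml = 0.2)  # 75000
#' @export
copies_to_concentration <- function(copies_per_reaction,
                                    rt_input_fraction = 1 / 15,
                                    biofluid_volume_ml = 0.2) {
  if (any(copies_per_reaction < 0)) stop_mirplat("copies must be >= 0")
  if (rt_input_fraction <= 0 || rt_input_fraction > 1)
    stop_mirplat("rt_input_fraction must lie in (0, 1]")
  if (biofluid_volume_ml <= 0) stop_mirplat("biofluid_volume_ml must be positive")
  copies_per_reaction / rt_input_fraction / biofluid_volume_ml
}

#' Spike-in set
#'
#' Identifies control rows of a Ct matrix used for residual-Ct
#' normalization: exogenous RNA spike-ins and/or inter-plate calibrators.
#'
#' @param spike_ids control row identifiers (non-empty)
#' @param role `"rna_spike"` or `"interplate_calibrator"`
#' @return a `spike_in_set` list
#' @export
spike_in_set <- function(spike_ids, role = c("rna_spike", "interplate_calibrator")) {
  role <- match.arg(role)
  spike_ids <- unique(as.character(spike_ids))
  if (length(spike_ids) == 0L) stop_mirplat("spike_ids must be non-empty")
  structure(list(spike_ids = spike_ids, role = role), class = "spike_in_set")
}

#' Residual-Ct spike-in normalization
#'
#' For each run, a normalization factor is the mean over control rows of
#' that control's residual Ct — its Ct in the run minus its average over
#' all runs. The factor is subtracted from every raw Ct in the run, and
#' control rows are dropped from the output. With several controls the
#' per-control residuals are combined by their arithmetic mean. The same
#' residual-subtraction rule serves both RNA spike-in controls and RT /
#' inter-plate calibrator assays; only the control ids differ.
#'
#' Residuals of each control sum to zero across runs, so the across-run
#' mean of a control's normalized Ct equals its raw across-run average.
#' Because the factors are residuals against the across-run average, a
#' constant plate shift `c` applied to one of `k` runs is removed up to
#' the unavoidable re-centering remainder `c / k` (which vanishes as the
#' number of runs grows); the run-to-run spread it caused is what the
#' normalization eliminates.
#'
#' @param matrix a ct-scaled [expr_matrix()] containing the control rows
#' @param spikes a [spike_in_set()] (or character vector of control ids);
#'   controls must be unmasked in every run
#' @return a ct-scaled [expr_matrix()] without the control rows
#' @export
spikein_normalize_ct <- function(matrix, spikes) {
  if (!inherits(matrix, "expr_matrix") || expr_scale(matrix) != "ct")
    stop_mirplat("'matrix' must be a ct-scaled expr_matrix")
  ids <- if (inherits(spikes, "spike_in_set")) spikes$spike_ids else as.character(spikes)
  missing_rows <- setdiff(ids, mirna_ids(matrix))
  if (length(missing_rows) > 0L)
    stop_mirplat("spike row(s) absent from matrix: %s",
                 paste(missing_rows, collapse = ", "))
  vals <- unclass(matrix)
  sp <- vals[ids, , drop = FALSE]
  if (anyNA(sp)) {
    bad <- which(is.na(sp), arr.ind = TRUE)[1L, ]
    stop_mirplat("spike '%s' is not detected in run '%s'",
                 ids[bad[1L]], colnames(sp)[bad[2L]])
  }
  residuals <- sp - rowMeans(sp)               # per spike, per run
  factor <- colMeans(residuals)                # per run
  out <- sweep(vals, 2L, factor, "-")
  out <- out[setdiff(rownames(out), ids), , drop = FALSE]
  expr_matrix(out, scale = "ct")
}

#' Three-step hybridization-count normalization
#'
#' The standard probe-hybridization (nCounter-style) pipeline, applied
#' per run: (a) subtract the geometric mean of the negative-control
#' probes (background), clamping at zero; (b) scale so the run's
#' positive-control geometric mean matches the across-run average of
#' positive-control geometric means; (c) scale again so the geometric
#' mean of the run's `top_n` most highly expressed endogenous probes
#' matches the across-run average of those per-run top-`top_n` geometric
#' means. Control rows are dropped from the output.
#'
#' Geometric means in steps (b) and (c) are computed over strictly
#' positive values; the top-`top_n` selection in (c) is by
#' background-subtracted, positive-control-scaled value within each run,
#' with ties broken by miRNA id for determinism.
#'
#' @param raw a counts-scaled [expr_matrix()] containing control rows
#' @param neg_ids,pos_ids negative / positive control row ids
#' @param top_n number of top endogenous probes for step (c); default 100
#' @return an [expr_matrix()] of `normalized_counts` without control rows
#' @export
nanostring_normalize <- function(raw, neg_ids, pos_ids, top_n = 100L) {
  if (!inherits(raw, "expr_matrix") || expr_scale(raw) != "counts")
    stop_mirplat("'raw' must be a counts-scaled expr_matrix")
  vals <- unclass(raw)
  missing_rows <- setdiff(c(neg_ids, pos_ids), rownames(vals))
  if (length(missing_rows) > 0L)
    stop_mirplat("control row(s) absent: %s", paste(missing_rows, collapse = ", "))
  if (anyNA(vals[c(neg_ids, pos_ids), ]))
    stop_mirplat("control rows must be unmasked in every run")
  endo_ids <- setdiff(rownames(vals), c(neg_ids, pos_ids))
  if (length(endo_ids) < top_n)
    stop_mirplat("need >= top_n (%d) endogenous rows, have %d",
                 top_n, length(endo_ids))

  # (a) background subtraction; all-zero negatives mean zero background
  background <- apply(vals[neg_ids, , drop = FALSE], 2L, geomean)
  background[is.na(background)] <- 0
  sub <- pmax(sweep(vals, 2L, background, "-"), 0)

  # (b) positive-control scaling
  pos_gm <- apply(sub[pos_ids, , drop = FALSE], 2L, geomean)
  if (anyNA(pos_gm) || any(pos_gm == 0))
    stop_mirplat("positive-control geometric mean is zero in run '%s'",
                 colnames(vals)[which(is.na(pos_gm) | pos_gm == 0)[1L]])
  pos_factor <- mean(pos_gm) / pos_gm
  scaled <- sweep(sub, 2L, pos_factor, "*")

  # (c) top-n content scaling (endogenous rows only)
  endo <- scaled[endo_ids, , drop = FALSE]
  ord <- order(rownames(endo))                  # lexicographic tie-break
  endo <- endo[ord, , drop = FALSE]
  top_gm <- apply(endo, 2L, function(col) {
    top <- col[order(-col)][seq_len(top_n)]     # stable: ties by row order
    if (sum(top > 0, na.rm = TRUE) < top_n)
      stop_mirplat("fewer than top_n positive values after background subtraction")
    geomean(top)
  })
  content_factor <- mean(top_gm) / top_gm
  out <- sweep(endo, 2L, content_factor, "*")
  expr_matrix(out[endo_ids, , drop = FALSE], scale = "normalized_counts")
}

#' Reads-per-million normalization
#'
#' Scales each run so its values sum to one million:
#' `value / run_total * 1e6`, where the total is over unmasked cells.
#' The within-run depth normalization standard for small-RNA sequencing.
#'
#' @param matrix a counts-scaled [expr_matrix()]
#' @return an [expr_matrix()] on the `rpm` scale
#' @export
rpm_normalize <- function(matrix) {
  if (!inherits(matrix, "expr_matrix") || expr_scale(matrix) != "counts")
    stop_mirplat("'matrix' must be a counts-scaled expr_matrix")
  vals <- unclass(matrix)
  totals <- colSums(vals, na.rm = TRUE)
  if (any(totals == 0))
    stop_mirplat("run '%s' has zero total mapped reads",
                 colnames(vals)[which(totals == 0)[1L]])
  expr_matrix(sweep(vals, 2L, totals, "/") * 1e6, scale = "rpm")
}
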