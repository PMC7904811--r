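#' Expression matrices with explicit not-detected semantics
#'
#' An `expr_matrix` holds miRNA-by-run measurements on a declared scale.
#' Cells where the platform reported nothing ("not detected") are stored as
#' `NA` and are distinct from numeric zero: a sequenced miRNA with zero
#' mapped reads is an observed value of 0, while a qPCR assay that never
#' amplified carries no number at all. Masking of detectable-but-unreliable
#' cells is done explicitly via [apply_lod()].
#'
#' Scales and their validation rules:
#' * `ct` — qPCR threshold cycles; unmasked values must lie in (0, 45].
#' * `counts` — non-negative integers (sequencing reads or probe counts).
#' * `copies`, `copies_per_ml`, `rpm`, `normalized_counts` — non-negative
#'   reals.
#'
#' @param values numeric matrix (miRNA rows x run columns); `NA` marks a
#'   not-detected cell
#' @param scale one of `"ct"`, `"counts"`, `"copies"`, `"copies_per_ml"`,
#'   `"rpm"`, `"normalized_counts"`
#' @param mirna_ids,run_ids row and column identifiers; default to the
#'   dimnames of `values`
#' @return an object of class `expr_matrix`: a numeric matrix with a
#'   `scale` attribute and unique dimnames
#' @examples
#' m <- expr_matrix(matrix(c(10, 0, NA, 25), 2, 2,
#'                         dimnames = list(c("hsa-miR-16-5p", "hsa-miR-21-5p"),
#'                                         c("run1", "run2"))),
#'                  scale = "counts")
#' n_detected(m)
#' @export
expr_matrix <- function(values, scale, mirna_ids = rownames(values),
                        run_ids = colnames(values)) {
  scale <- match.arg(scale, expr_scales())
  if (!is.matrix(values) || !is.numeric(values))
    stop_mirplat("'values' must be a numeric matrix")
  if (is.null(mirna_ids) || is.null(run_ids))
    stop_mirplat("miRNA and run identifiers are required")
  mirna_ids <- as.character(mirna_ids)
  run_ids <- as.character(run_ids)
  if (length(mirna_ids) != nrow(values) || length(run_ids) != ncol(values))
    stop_mirplat("identifier lengths do not match matrix dimensions")
  if (anyDuplicated(mirna_ids))
    stop_mirplat("duplicate miRNA id(s): %s",
                 paste(unique(mirna_ids[duplicated(mirna_ids)]), collapse = ", "))
  if (anyDuplicated(run_ids))
    stop_mirplat("duplicate run id(s): %s",
                 paste(unique(run_ids[duplicated(run_ids)]), collapse = ", "))
  dimnames(values) <- list(mirna_ids, run_ids)
  validate_scale_values(values, scale)
  structure(values, scale = scale, class = c("expr_matrix", "matrix", "array"))
}

expr_scales <- function() {
  c("ct", "counts", "copies", "copies_per_ml", "rpm", "normalized_counts")
}

validate_scale_values <- function(values, scale) {
  v <- values[!is.na(values)]
  if (length(v) == 0L) return(invisible(TRUE))
  if (any(!is.finite(v)))
    stop_mirplat("non-finite unmasked values are not allowed")
  if (scale == "ct") {
    if (any(v <= 0 | v > 45))
      stop_mirplat("Ct values must lie in (0, 45]; offending value %g", v[v <= 0 | v > 45][1])
  } else if (scale == "counts") {
    if (any(v < 0) || any(abs(v - round(v)) > 1e-8))
      stop_mirplat("counts must be non-negative integers")
  } else {
    if (any(v < 0))
      stop_mirplat("'%s' values must be non-negative", scale)
  }
  invisible(TRUE)
}

#' @rdname expr_matrix
#' @param x an `expr_matrix`
#' @export
expr_scale <- function(x) attr(x, "scale")

#' @rdname expr_matrix
#' @export
mirna_ids <- function(x) rownames(x)

#' @rdname expr_matrix
#' @export
run_ids <- function(x) colnames(x)

#' @rdname expr_matrix
#' @export
not_detected <- function(x) is.na(unclass(x))

#' @rdname expr_matrix
#' @export
n_detected <- function(x) rowSums(!is.na(unclass(x)))

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d miRNAs x %d runs, scale = %s, %d not-detected cell(s)\n",
              nrow(x), ncol(x), expr_scale(x), sum(is.na(x))))
  utils::str(unclass(x), give.attr = FALSE)
  invisible(x)
}

# rebuild (and revalidate) after any structural surgery on the raw matrix
as_expr_matrix <- function(values, scale) expr_matrix(values, scale)

#' Platform specification
#'
#' Describes a quantification platform: its technology, the set of miRNAs
#' its panel can assay, its limit-of-detection rule and the native scale of
#' its raw output. The LOD rule type must match the technology: qPCR
#' platforms censor at a maximal Ct (a cell passes when Ct is strictly
#' below `max_ct`), while counting platforms require a minimal read/probe
#' count (a cell passes when its count is at least `min_reads`).
#'
#' @param name platform label
#' @param technology `"qpcr"`, `"hybridization"` or `"sequencing"`
#' @param panel character vector of assayable miRNA ids (non-empty)
#' @param lod_rule a one-element named list, `list(max_ct = 40)` for qPCR or
#'   `list(min_reads = 5)` for counting technologies
#' @param scale native raw scale of the platform output
#' @return an object of class `platform_spec`
#' @examples
#' platform_spec("seq", "sequencing", c("hsa-miR-16-5p", "hsa-miR-21-5p"),
#'               lod_rule = list(min_reads = 5), scale = "counts")
#' @export
platform_spec <- function(name, technology, panel, lod_rule, scale) {
  technology <- match.arg(technology, c("qpcr", "hybridization", "sequencing"))
  scale <- match.arg(scale, expr_scales())
  panel <- unique(as.character(panel))
  if (length(panel) == 0L) stop_mirplat("panel must be non-empty")
  if (!is.list(lod_rule) || length(lod_rule) != 1L ||
      !names(lod_rule) %in% c("max_ct", "min_reads"))
    stop_mirplat("lod_rule must be list(max_ct = ...) or list(min_reads = ...)")
  rule <- names(lod_rule)
  if (technology == "qpcr" && rule != "max_ct")
    stop_mirplat("qPCR platforms use a max_ct LOD rule")
  if (technology != "qpcr" && rule != "min_reads")
    stop_mirplat("counting platforms use a min_reads LOD rule")
  assert_scalar_number(lod_rule[[1]], rule, positive = TRUE)
  structure(list(name = as.character(name), technology = technology,
                 panel = panel, lod_rule = lod_rule, scale = scale),
            class = "platform_spec")
}

#' @export
print.platform_spec <- function(x, ...) {
  cat(sprintf("platform_spec '%s': %s, panel of %d miRNAs, LOD %s = %g, scale = %s\n",
              x$name, x$technology, length(x$panel),
              names(x$lod_rule), x$lod_rule[[1]], x$scale))
  invisible(x)
}

#' Replicate run set
#'
#' Bundles an expression matrix with its platform and a replicate-group
#' label asserting that the run columns are independent technical
#' replicates of one sample. Replicate analyses (CV, LLOQ, concordance)
#' expect at least three runs in a group; construction warns below that.
#'
#' @param matrix an [expr_matrix()]
#' @param platform a [platform_spec()]; every miRNA row must belong to the
#'   platform panel
#' @param replicate_group label for the replicated sample
#' @return an object of class `run_set`
#' @export
run_set <- function(matrix, platform, replicate_group = "sample") {
  if (!inherits(matrix, "expr_matrix")) stop_mirplat("'matrix' must be an expr_matrix")
  if (!inherits(platform, "platform_spec")) stop_mirplat("'platform' must be a platform_spec")
  outside <- setdiff(mirna_ids(matrix), platform$panel)
  if (length(outside) > 0L)
    stop_mirplat("miRNA(s) not in the '%s' panel: %s%s", platform$name,
                 paste(utils::head(outside, 3), collapse = ", "),
                 if (length(outside) > 3) ", ..." else "")
  if (ncol(matrix) < 3L)
    warning("fewer than three runs: replicate analyses need >= 3 independent runs",
            call. = FALSE)
  structure(list(matrix = matrix, platform = platform,
                 replicate_group = as.character(replicate_group)),
            class = "run_set")
}

#' Read an expression matrix from delimited text
#'
#' Expects a header row of run ids and a first column of miRNA ids. Cells
#' equal to `na_token` become not-detected; all other cells must parse as
#' numbers valid for `scale` (see [expr_matrix()] for the per-scale rules).
#'
#' @param path file path
#' @param scale declared scale of the stored values
#' @param na_token string marking a not-detected cell (default `"NA"`)
#' @param sep field separator (default tab)
#' @return an [expr_matrix()]
#' @seealso [write_expression_matrix()] for the exact-round-trip writer
#' @export
read_expression_matrix <- function(path, scale, na_token = "NA", sep = "\t") {
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                           check.names = FALSE, colClasses = "character",
                           comment.char = "", stringsAsFactors = FALSE,
                           na.strings = character(0))
  if (ncol(raw) < 2L) stop_mirplat("expected at least one run column in '%s'", path)
  ids <- raw[[1L]]
  run_ids <- colnames(raw)[-1L]
  vals <- matrix(NA_real_, nrow = nrow(raw), ncol = length(run_ids),
                 dimnames = list(ids, run_ids))
  for (j in seq_along(run_ids)) {
    cell <- raw[[j + 1L]]
    keep <- cell != na_token
    num <- suppressWarnings(as.numeric(cell[keep]))
    if (anyNA(num)) {
      bad <- which(keep)[which(is.na(num))[1L]]
      stop_mirplat("non-numeric cell at row %d (miRNA '%s'), column '%s': '%s'",
                   bad, ids[bad], run_ids[j], cell[bad])
    }
    vals[keep, j] <- num
  }
  expr_matrix(vals, scale = scale)
}

#' Write an expression matrix as delimited text
#'
#' Values are serialized with 17 significant digits so that
#' write-then-read reproduces the matrix exactly (values, mask and
#' orderings).
#'
#' @param x an [expr_matrix()]
#' @param path output file path
#' @inheritParams read_expression_matrix
#' @return `path`, invisibly
#' @export
write_expression_matrix <- function(x, path, na_token = "NA", sep = "\t") {
  if (!inherits(x, "expr_matrix")) stop_mirplat("'x' must be an expr_matrix")
  fmt <- function(v) ifelse(is.na(v), na_token, sprintf("%.17g", v))
  body <- apply(unclass(x), 2L, fmt)
  if (nrow(x) == 1L) body <- matrix(body, nrow = 1L)
  lines <- c(paste(c("mirna_id", run_ids(x)), collapse = sep),
             vapply(seq_len(nrow(x)), function(i)
               paste(c(mirna_ids(x)[i], body[i, ]), collapse = sep), ""))
  writeLines(lines, path)
  invisible(path)
}

#' Apply a platform's limit-of-detection rule
#'
#' Masks cells failing the platform LOD: for qPCR, cells with
#' `Ct >= max_ct` (the usual rule "Ct < 40" passes); for counting
#' platforms, cells with `count < min_reads` (a count of exactly
#' `min_reads`, e.g. 5 reads, passes). Surviving values are unchanged and
#' already-masked cells stay masked, so the operation is idempotent.
#'
#' @param matrix an [expr_matrix()] on the platform's native scale
#' @param spec a [platform_spec()]
#' @return an [expr_matrix()] with failing cells masked
#' @export
apply_lod <- function(matrix, spec) {
  if (!inherits(matrix, "expr_matrix")) stop_mirplat("'matrix' must be an expr_matrix")
  if (!inherits(spec, "platform_spec")) stop_mirplat("'spec' must be a platform_spec")
  if (expr_scale(matrix) != spec$scale)
    stop_mirplat("matrix scale '%s' does not match platform native scale '%s'",
                 expr_scale(matrix), spec$scale)
  vals <- unclass(matrix)
  rule <- names(spec$lod_rule)
  if (rule == "max_ct") {
    if (expr_scale(matrix) != "ct")
      stop_mirplat("max_ct rule requires a ct-scaled matrix")
    vals[!is.na(vals) & vals >= spec$lod_rule$max_ct] <- NA_real_
  } else {
    if (!expr_scale(matrix) %in% c("counts", "rpm", "normalized_counts"))
      stop_mirplat("min_reads rule requires a count-like matrix")
    vals[!is.na(vals) & vals < spec$lod_rule$min_reads] <- NA_real_
  }
  expr_matrix(vals, scale = expr_scale(matrix))
}
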