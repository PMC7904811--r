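# miRNA id harmonization is by exact string match after lowercasing and
# whitespace trimming; aliases across miRBase releases are NOT resolved
canonical_mirna_id <- function(ids) tolower(trimws(as.character(ids)))

#' Cross-platform overlap of quantifiable miRNA sets
#'
#' Given one above-LLOQ miRNA set per platform, counts the miRNAs
#' detected by each exact platform combination (disjoint membership
#' patterns over the union, the numbers behind an UpSet/Venn display),
#' plus the union size and, for each k, the number of miRNAs detected by
#' at least k platforms. Ids are canonicalized (lowercase, trimmed)
#' before matching.
#'
#' @param platform_sets named list (>= 2 platforms) of character vectors
#'   of quantifiable miRNA ids
#' @return an `overlap_result`: list with `platform_sets` (canonicalized),
#'   `membership_counts` (named by `+`-joined platform combinations,
#'   non-empty patterns only), `union_size`, `k_way_counts`
#' @examples
#' overlap_analysis(list(A = c("m1", "m2", "m3"), B = c("m2", "m3", "m4")))
#' @export
overlap_analysis <- function(platform_sets) {
  if (!is.list(platform_sets) || length(platform_sets) < 2L ||
      is.null(names(platform_sets)) || any(names(platform_sets) == ""))
    stop_mirplat("platform_sets must be a named list of >= 2 platforms")
  sets <- lapply(platform_sets, function(s) unique(canonical_mirna_id(s)))
  ids <- sort(unique(unlist(sets, use.names = FALSE)))
  membership <- vapply(sets, function(s) ids %in% s, logical(length(ids)))
  if (length(ids) == 1L) membership <- matrix(membership, nrow = 1L,
                                              dimnames = list(NULL, names(sets)))
  pattern <- apply(membership, 1L, function(row)
    paste(names(sets)[row], collapse = "+"))
  counts <- table(pattern)
  k_each <- rowSums(membership)
  k_way <- vapply(seq_along(sets), function(k) sum(k_each >= k), 0L)
  names(k_way) <- sprintf(">=%d", seq_along(sets))
  structure(list(platform_sets = sets,
                 membership_counts = stats::setNames(as.integer(counts),
                                                     names(counts)),
                 union_size = length(ids),
                 k_way_counts = k_way),
            class = "overlap_result")
}

#' Panel-content accounting for detection discrepancies
#'
#' For every ordered platform pair (A, B), splits the miRNAs quantified
#' by A but not by B into those absent from B's panel (B could never
#' have assayed them) versus those on B's panel but not quantified —
#' separating panel-content gaps from genuine sensitivity differences.
#'
#' @param sets named list of above-LLOQ id sets per platform
#' @param panels named list of panel content per platform (same names);
#'   each detected set must be a subset of its own panel
#' @return a `panel_accounting` data.frame with columns `platform_a`,
#'   `platform_b`, `detected_by_a_not_b`, `absent_from_b_panel`,
#'   `present_but_undetected`, `frac_absent`
#' @export
panel_accounting <- function(sets, panels) {
  if (!setequal(names(sets), names(panels)))
    stop_mirplat("sets and panels must cover the same platforms")
  sets <- lapply(sets, function(s) unique(canonical_mirna_id(s)))
  panels <- lapply(panels, function(p) unique(canonical_mirna_id(p)))
  for (p in names(sets)) {
    stray <- setdiff(sets[[p]], panels[[p]])
    if (length(stray) > 0L)
      stop_mirplat("platform '%s' reports miRNA(s) outside its own panel: %s",
                   p, paste(utils::head(stray, 3), collapse = ", "))
  }
  pairs <- expand.grid(platform_a = names(sets), platform_b = names(sets),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$platform_a != pairs$platform_b, , drop = FALSE]
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs$platform_a[i]; b <- pairs$platform_b[i]
    only_a <- setdiff(sets[[a]], sets[[b]])
    absent <- setdiff(only_a, panels[[b]])
    data.frame(platform_a = a, platform_b = b,
               detected_by_a_not_b = length(only_a),
               absent_from_b_panel = length(absent),
               present_but_undetected = length(only_a) - length(absent),
               frac_absent = if (length(only_a) > 0)
                 length(absent) / length(only_a) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("panel_accounting", "data.frame")
  out
}

#' Assemble the platform comparison report
#'
#' One summary row per platform — panel size, average pairwise ccc,
#' number of miRNAs above the LLOQ and the median %CV of those miRNAs —
#' plus the cross-platform overlap summary. Platforms whose CV trend
#' never dropped below the cutoff (`all_above_cutoff`) are reported with
#' zero quantifiable miRNAs and an exclusion note, the treatment given
#' to a platform whose measurement variability is too high for an LLOQ
#' to be calculated. Missing components leave explicit gaps (`NA`) and
#' increment the warning count rather than failing.
#'
#' @param runsets named list of [run_set()] objects, one per platform
#' @param lloq_results named list of [estimate_lloq()] /
#'   [lloq_pipeline()] results (with `stats` and `above_lloq` where
#'   available)
#' @param concordance_results named list of
#'   [pairwise_run_concordance()] results
#' @param overlap an [overlap_analysis()] result, or NULL
#' @return a `comparison_report`: list with `table` (data.frame),
#'   `overlap`, `notes`, `n_warnings`
#' @export
comparison_report <- function(runsets, lloq_results = list(),
                              concordance_results = list(), overlap = NULL) {
  if (length(runsets) == 0L || is.null(names(runsets)))
    stop_mirplat("runsets must be a named list")
  notes <- character(0)
  n_warnings <- 0L
  rows <- lapply(names(runsets), function(p) {
    rs <- runsets[[p]]
    ll <- lloq_results[[p]]
    cc <- concordance_results[[p]]
    n_above <- NA_integer_; med_cv <- NA_real_; lloq_val <- NA_real_
    if (is.null(ll)) {
      n_warnings <<- n_warnings + 1L
      notes <<- c(notes, sprintf("%s: no LLOQ result supplied", p))
    } else {
      lloq_val <- ll$lloq_value
      if (ll$boundary_flag == "all_above_cutoff") {
        n_above <- 0L
        notes <<- c(notes, sprintf(
          "%s: LLOQ could not be calculated (CV above the %.0f%% cutoff across the full range); platform excluded from quantifiable-set analyses",
          p, 100 * ll$cutoff))
      } else if (!is.null(ll$above_lloq)) {
        n_above <- length(ll$above_lloq)
        if (!is.null(ll$stats) && n_above > 0L) {
          sel <- ll$stats$mirna_id %in% ll$above_lloq
          med_cv <- stats::median(ll$stats$cv[sel], na.rm = TRUE) * 100
        }
      }
    }
    if (is.null(cc)) {
      n_warnings <<- n_warnings + 1L
      notes <<- c(notes, sprintf("%s: no concordance result supplied", p))
    }
    data.frame(platform = p,
               panel_size = length(rs$platform$panel),
               n_runs = ncol(rs$matrix),
               average_ccc = if (is.null(cc)) NA_real_ else cc$average_ccc,
               lloq_value = lloq_val,
               n_above_lloq = n_above,
               median_pct_cv_above_lloq = med_cv,
               stringsAsFactors = FALSE)
  })
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  structure(list(table = table, overlap = overlap, notes = notes,
                 n_warnings = n_warnings),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(format_comparison_report(x), sep = "\n")
  invisible(x)
}

#' Render a comparison report as text lines
#'
#' Deterministic serialization: regenerating the report from identical
#' inputs yields byte-identical lines.
#'
#' @param report a [comparison_report()]
#' @return character vector of report lines
#' @export
format_comparison_report <- function(report) {
  stopifnot(inherits(report, "comparison_report"))
  t <- report$table
  lines <- c("Platform comparison",
             "===================",
             sprintf("%-14s %10s %6s %8s %12s %12s %14s",
                     "platform", "panel", "runs", "avg_ccc", "lloq",
                     "n_above_lloq", "median_%cv"))
  for (i in seq_len(nrow(t))) {
    lines <- c(lines, sprintf("%-14s %10d %6d %8s %12s %12s %14s",
      t$platform[i], t$panel_size[i], t$n_runs[i],
      ifelse(is.na(t$average_ccc[i]), "NA", sprintf("%.3f", t$average_ccc[i])),
      ifelse(is.na(t$lloq_value[i]), "NA", sprintf("%.4g", t$lloq_value[i])),
      ifelse(is.na(t$n_above_lloq[i]), "NA", sprintf("%d", t$n_above_lloq[i])),
      ifelse(is.na(t$median_pct_cv_above_lloq[i]), "NA",
             sprintf("%.1f", t$median_pct_cv_above_lloq[i]))))
  }
  if (!is.null(report$overlap)) {
    ov <- report$overlap
    lines <- c(lines, "",
               sprintf("Union of quantifiable miRNAs: %d", ov$union_size),
               sprintf("Detected by >= k platforms: %s",
                       paste(sprintf("%s:%d", names(ov$k_way_counts),
                                     ov$k_way_counts), collapse = " ")),
               "Membership patterns:",
               sprintf("  %-40s %d", names(ov$membership_counts),
                       ov$membership_counts))
  }
  if (length(report$notes) > 0L)
    lines <- c(lines, "", "Notes:", paste0("  - ", report$notes))
  lines
}
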