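#' Build a pipeline configuration
#'
#' Single configuration object driving the end-to-end evaluation
#' (simulate -> normalize -> LLOQ -> concordance -> saturation ->
#' cross-platform comparison) on synthetic multi-platform data generated
#' from one shared ground truth. Every random stage derives its stream
#' from the single `seed`, so a configuration fully determines its
#' outputs.
#'
#' @param seed master integer seed
#' @param n_mirnas,mu_log10,sigma_log10 ground-truth profile parameters
#'   (see [simulate_truth()])
#' @param n_runs replicate runs per platform
#' @param seq_model a [seq_noise_model()]
#' @param qpcr_model a [qpcr_noise_model()]
#' @param hyb_model a [hyb_noise_model()]
#' @param qpcr_scale copies-per-reaction scale for [simulate_qpcr_runs()]
#' @param span,cutoff,min_runs LLOQ parameters
#' @param depth_grid subsampling grid for the saturation analysis, as
#'   fractions of the miRNA-mapped read total per run
#' @param lod,n_resamples detection-curve parameters
#' @return a validated `pipeline_config` list
#' @export
pipeline_config <- function(seed = 1L,
                            n_mirnas = 600L, mu_log10 = 2, sigma_log10 = 1,
                            n_runs = 4L,
                            seq_model = seq_noise_model(depth = 2e6, rho = 0.125,
                                                        mirna_fraction = 0.09),
                            qpcr_model = qpcr_noise_model(),
                            hyb_model = hyb_noise_model(),
                            qpcr_scale = 0.05,
                            span = 0.75, cutoff = 0.5, min_runs = 3L,
                            depth_grid_fraction = c(0.1, 0.2, 0.4, 0.7, 1),
                            lod = 5L, n_resamples = 10L) {
  cfg <- list(seed = as.integer(seed), n_mirnas = as.integer(n_mirnas),
              mu_log10 = mu_log10, sigma_log10 = sigma_log10,
              n_runs = as.integer(n_runs), seq_model = seq_model,
              qpcr_model = qpcr_model, hyb_model = hyb_model,
              qpcr_scale = qpcr_scale, span = span, cutoff = cutoff,
              min_runs = as.integer(min_runs),
              depth_grid_fraction = depth_grid_fraction,
              lod = as.integer(lod), n_resamples = as.integer(n_resamples))
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  if (is.null(cfg$seed)) stop_mirplat("config must carry an explicit seed")
  if (cfg$cutoff <= 0 || cfg$cutoff >= 1)
    stop_mirplat("cutoff must lie in (0, 1)")
  if (cfg$n_runs < cfg$min_runs)
    stop_mirplat("n_runs (%d) below min_runs (%d)", cfg$n_runs, cfg$min_runs)
  if (any(cfg$depth_grid_fraction <= 0 | cfg$depth_grid_fraction > 1))
    stop_mirplat("depth_grid_fraction entries must lie in (0, 1]")
  for (f in cfg$files)
    if (!file.exists(f)) stop_mirplat("referenced file does not exist: %s", f)
  invisible(TRUE)
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields override the [pipeline_config()] defaults; the nested
#' `seq_model`, `qpcr_model` and `hyb_model` blocks are passed to their
#' constructors. Referenced files (e.g. panel lists under `files`) are
#' checked for existence at validation time, before any stage runs.
#'
#' @param path YAML file path
#' @return a `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_mirplat("config file does not exist: %s", path)
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), setdiff(names(formals(pipeline_config)),
                                        c("seq_model", "qpcr_model", "hyb_model")))]
  if (!is.null(y$seq_model)) args$seq_model <- do.call(seq_noise_model, y$seq_model)
  if (!is.null(y$qpcr_model)) args$qpcr_model <- do.call(qpcr_noise_model, y$qpcr_model)
  if (!is.null(y$hyb_model)) args$hyb_model <- do.call(hyb_noise_model, y$hyb_model)
  cfg <- do.call(pipeline_config, args)
  if (!is.null(y$files)) { cfg$files <- unlist(y$files); validate_pipeline_config(cfg) }
  cfg
}

#' Run the full evaluation pipeline
#'
#' Simulates three platforms (sequencing, qPCR, hybridization counter)
#' from one shared ground truth, normalizes each with its native scheme
#' (RPM; spike-in-free relative linearization for the synthetic qPCR
#' arm; three-step hybridization normalization), runs the LLOQ and
#' concordance analyses per platform, the depth-saturation analysis on
#' the sequencing arm, and the cross-platform overlap and comparison
#' report. All artifacts are written under `out_dir` as TSV/JSON/text,
#' and a manifest records every artifact with its MD5 checksum and the
#' configuration hash; identical configurations reproduce identical
#' manifests.
#'
#' @param config a [pipeline_config()]
#' @param out_dir output directory (created if absent)
#' @param quiet suppress stage progress messages
#' @return (invisibly) list with `manifest` (data.frame), `report`,
#'   `lloq`, `concordance`, `overlap`, `saturation`, `warnings`
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  validate_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(fmt, ...) if (!quiet) message(sprintf(paste0("[mirplat] ", fmt), ...))
  warn_log <- character(0)
  note_warning <- function(w) { warn_log <<- c(warn_log, conditionMessage(w)) }

  # -- simulate -------------------------------------------------------------
  say("stage simulate: %d miRNAs, %d runs/platform, seed %d",
      config$n_mirnas, config$n_runs, config$seed)
  truth <- simulate_truth(config$n_mirnas, config$mu_log10, config$sigma_log10,
                          seed = config$seed)
  seq_raw <- simulate_seq_runs(truth, config$seq_model, config$n_runs,
                               seed = config$seed + 1L)
  qpcr_raw <- simulate_qpcr_runs(truth, config$qpcr_model, config$qpcr_scale,
                                 config$n_runs, seed = config$seed + 2L)
  hyb <- simulate_hyb_runs(truth, config$hyb_model, config$n_runs,
                           seed = config$seed + 3L)

  panel <- truth$mirna_ids
  specs <- list(
    seq = platform_spec("seq", "sequencing", panel,
                        list(min_reads = config$lod), "counts"),
    qpcr = platform_spec("qpcr", "qpcr", panel,
                         list(max_ct = config$qpcr_model$max_ct), "ct"),
    hyb = platform_spec("hyb", "hybridization", c(panel, hyb$neg_ids, hyb$pos_ids),
                        list(min_reads = config$lod), "counts"))

  truth_path <- file.path(out_dir, "truth.tsv")
  utils::write.table(
    data.frame(mirna_id = truth$mirna_ids,
               true_abundance = sprintf("%.17g", truth$true_abundance)),
    truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write_expression_matrix(seq_raw, file.path(out_dir, "seq_raw_counts.tsv"))
  write_expression_matrix(qpcr_raw, file.path(out_dir, "qpcr_raw_ct.tsv"))
  write_expression_matrix(hyb$matrix, file.path(out_dir, "hyb_raw_counts.tsv"))

  # -- normalize ------------------------------------------------------------
  say("stage normalize")
  seq_rpm <- rpm_normalize(seq_raw)
  qpcr_lin <- linearize(qpcr_raw, ct_ref = config$qpcr_model$max_ct)
  hyb_norm <- nanostring_normalize(hyb$matrix, hyb$neg_ids, hyb$pos_ids,
                                   top_n = min(100L, config$n_mirnas))
  write_expression_matrix(seq_rpm, file.path(out_dir, "seq_rpm.tsv"))
  write_expression_matrix(qpcr_lin, file.path(out_dir, "qpcr_linear.tsv"))
  write_expression_matrix(hyb_norm, file.path(out_dir, "hyb_normalized.tsv"))

  # -- lloq -----------------------------------------------------------------
  say("stage lloq (span %.2f, cutoff %.0f%% CV)", config$span, 100 * config$cutoff)
  linear_mats <- list(seq = seq_raw, qpcr = qpcr_lin, hyb = hyb_norm)
  lloq_results <- lapply(linear_mats, function(m) {
    tryCatch(withCallingHandlers(
      lloq_pipeline(m, min_runs = config$min_runs, span = config$span,
                    cutoff = config$cutoff),
      warning = function(w) { note_warning(w); invokeRestart("muffleWarning") }),
      error = function(e) { warn_log <<- c(warn_log, conditionMessage(e)); NULL })
  })
  trend_rows <- do.call(rbind, lapply(names(lloq_results), function(p) {
    ll <- lloq_results[[p]]
    if (is.null(ll)) return(NULL)
    data.frame(platform = p, log10_mean = sprintf("%.10g", ll$trend$grid),
               fitted_cv = sprintf("%.10g", ll$trend$fitted_cv))
  }))
  utils::write.table(trend_rows, file.path(out_dir, "cv_trends.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  above_lines <- unlist(lapply(names(lloq_results), function(p) {
    ll <- lloq_results[[p]]
    if (is.null(ll)) character(0) else sprintf("%s\t%s", p, ll$above_lloq)
  }))
  writeLines(c("platform\tmirna_id", above_lines),
             file.path(out_dir, "above_lloq.tsv"))

  # -- concordance ----------------------------------------------------------
  say("stage concordance")
  ccc_inputs <- list(seq = seq_rpm, qpcr = qpcr_lin, hyb = hyb_norm)
  ccc_results <- lapply(ccc_inputs, function(m)
    withCallingHandlers(pairwise_run_concordance(m, log_transform = TRUE),
                        warning = function(w) { note_warning(w); invokeRestart("muffleWarning") }))
  ccc_tab <- data.frame(platform = names(ccc_results),
                        average_ccc = sprintf("%.10g", vapply(ccc_results,
                          function(x) x$average_ccc, 0)))
  utils::write.table(ccc_tab, file.path(out_dir, "ccc.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # -- saturation (sequencing arm) ------------------------------------------
  say("stage saturate")
  seq_total <- min(colSums(unclass(seq_raw), na.rm = TRUE))
  grid <- unique(round(config$depth_grid_fraction * seq_total))
  sat_curve <- detection_curve(seq_raw, grid, lod = config$lod,
                               n_resamples = config$n_resamples,
                               seed = config$seed + 4L)
  sat_depth <- saturation_depth(sat_curve)
  utils::write.table(
    data.frame(depth = sat_curve$depth_grid,
               detected_mean = sprintf("%.10g", sat_curve$detected_mean),
               detected_sd = sprintf("%.10g", sat_curve$detected_sd)),
    file.path(out_dir, "saturation_curve.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  # -- compare --------------------------------------------------------------
  say("stage compare")
  sets <- lapply(lloq_results, function(ll)
    if (is.null(ll)) character(0) else ll$above_lloq)
  overlap <- overlap_analysis(sets)
  panels <- lapply(specs, function(s) s$panel)
  accounting <- panel_accounting(sets, panels)
  utils::write.table(accounting, file.path(out_dir, "panel_accounting.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  runsets <- list(
    seq = run_set(seq_raw, specs$seq, "ref_sample"),
    qpcr = run_set(qpcr_raw, specs$qpcr, "ref_sample"),
    hyb = run_set(hyb$matrix, specs$hyb, "ref_sample"))
  report <- comparison_report(runsets, lloq_results, ccc_results, overlap)
  writeLines(format_comparison_report(report), file.path(out_dir, "report.txt"))
  jsonlite::write_json(
    list(union_size = overlap$union_size,
         k_way_counts = as.list(overlap$k_way_counts),
         membership_counts = as.list(overlap$membership_counts),
         saturation_depth = sat_depth,
         warnings = warn_log),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)

  # -- manifest -------------------------------------------------------------
  artifacts <- c("truth.tsv", "seq_raw_counts.tsv", "qpcr_raw_ct.tsv",
                 "hyb_raw_counts.tsv", "seq_rpm.tsv", "qpcr_linear.tsv",
                 "hyb_normalized.tsv", "cv_trends.tsv", "above_lloq.tsv",
                 "ccc.tsv", "saturation_curve.tsv", "panel_accounting.tsv",
                 "report.txt", "summary.json")
  md5 <- tools::md5sum(file.path(out_dir, artifacts))
  cfg_hash <- config_hash(config)
  manifest <- data.frame(artifact = artifacts, md5 = unname(md5),
                         stringsAsFactors = FALSE)
  manifest_lines <- c(sprintf("# config_hash\t%s", cfg_hash),
                      "artifact\tmd5",
                      sprintf("%s\t%s", manifest$artifact, manifest$md5))
  writeLines(manifest_lines, file.path(out_dir, "manifest.tsv"))
  say("done: %d artifacts, %d warning(s)", length(artifacts), length(warn_log))
  invisible(list(manifest = manifest, config_hash = cfg_hash, report = report,
                 lloq = lloq_results, concordance = ccc_results,
                 overlap = overlap, saturation = list(curve = sat_curve,
                                                      depth = sat_depth),
                 warnings = warn_log))
}

# MD5 of the deparsed configuration; stable across sessions for the same
# parameter values
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(unclass(config), control = "all"), tmp)
  unname(tools::md5sum(tmp))
}
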