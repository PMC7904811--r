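#' Simulate a ground-truth miRNA abundance profile
#'
#' Draws per-miRNA true abundances i.i.d. log-normal on the log10 scale:
#' `log10(abundance) ~ Normal(mu_log10, sigma_log10)`. With the default
#' `sigma_log10 = 1` the central +/- 3 SD of the population spans six
#' decades, matching the dynamic range that serum miRNA profiling
#' platforms report. `sigma_log10 = 0` gives the degenerate profile where
#' every abundance equals `10^mu_log10`.
#'
#' @param n_mirnas number of miRNAs (>= 1)
#' @param mu_log10 mean of log10 abundance (arbitrary relative units)
#' @param sigma_log10 SD of log10 abundance (>= 0)
#' @param seed integer seed; fixed seed gives bit-identical profiles
#' @return a `truth_profile`: list with `mirna_ids`, `true_abundance`,
#'   `mu_log10`, `sigma_log10`, `seed`. Identifiers are synthetic
#'   (`syn-mir-0001`, ...), not real miRBase names.
#' @export
simulate_truth <- function(n_mirnas, mu_log10 = 2, sigma_log10 = 1, seed = 1L) {
  if (!is.numeric(n_mirnas) || n_mirnas < 1) stop_mirplat("n_mirnas must be >= 1")
  if (sigma_log10 < 0) stop_mirplat("sigma_log10 must be >= 0")
  n_mirnas <- as.integer(n_mirnas)
  ab <- with_seed_or_current(seed, 10^stats::rnorm(n_mirnas, mu_log10, sigma_log10))
  structure(list(
    mirna_ids = sprintf("syn-mir-%04d", seq_len(n_mirnas)),
    true_abundance = ab,
    mu_log10 = mu_log10, sigma_log10 = sigma_log10, seed = seed
  ), class = "truth_profile")
}

#' Sequencing noise model
#'
#' Parameters of the Dirichlet-multinomial read-count model used by
#' [simulate_seq_runs()]. `depth` is the total sequencing depth per
#' library; only a fraction `mirna_fraction` of reads maps to mature
#' miRNAs (serum libraries map ~9% of reads to miRNAs, brain ~38%).
#' `rho` is the squared CV of the per-replicate compositional jitter:
#' across-replicate CV^2 of a low-proportion miRNA with mean count `mu`
#' is approximately `1/mu + rho`, so `rho` sets an abundance-independent
#' CV floor above Poisson shot noise. `rho` must stay below 0.25 for a
#' 50%-CV LLOQ to exist at finite abundance (the floor `sqrt(rho)` must
#' be under 0.5).
#'
#' @param depth total reads per library (>= 1)
#' @param rho overdispersion correlation in \[0, 0.25)
#' @param mirna_fraction fraction of reads mapping to mature miRNAs, (0, 1]
#' @return a `seq_noise_model` list
#' @export
seq_noise_model <- function(depth = 2e7, rho = 0, mirna_fraction = 0.09) {
  assert_scalar_number(depth, "depth", positive = TRUE)
  if (rho < 0 || rho >= 0.25)
    stop_mirplat("rho must lie in [0, 0.25) so the 50%% CV crossing exists")
  if (mirna_fraction <= 0 || mirna_fraction > 1)
    stop_mirplat("mirna_fraction must lie in (0, 1]")
  structure(list(depth = depth, rho = rho, mirna_fraction = mirna_fraction),
            class = "seq_noise_model")
}

#' qPCR noise model
#'
#' Standard-curve relationship plus noise for [simulate_qpcr_runs()]:
#' the number of template molecules entering RT is Poisson around the
#' expected copy number, and the measured Ct is
#' `intercept + slope * log10(copies) + Normal(0, sigma0 +
#' sigma_scale / sqrt(expected))`. The `sigma_scale` term is the minimal
#' mechanism producing the rising Ct variability observed near the assay
#' floor. Reactions sampling zero molecules, or with Ct at or above
#' `max_ct`, are censored (not detected).
#'
#' @param slope Ct change per log10 copies (negative; -3.32 at 100%
#'   amplification efficiency)
#' @param intercept Ct at a single template copy
#' @param sigma0 baseline Ct SD
#' @param sigma_scale extra Ct SD coefficient at low copy number
#' @param max_ct censoring bound (default 40)
#' @return a `qpcr_noise_model` list
#' @export
qpcr_noise_model <- function(slope = -3.32, intercept = 38, sigma0 = 0.1,
                             sigma_scale = 0.5, max_ct = 40) {
  if (slope >= 0) stop_mirplat("slope must be negative")
  if (sigma0 < 0 || sigma_scale < 0) stop_mirplat("sigma terms must be >= 0")
  assert_scalar_number(max_ct, "max_ct", positive = TRUE)
  structure(list(slope = slope, intercept = intercept, sigma0 = sigma0,
                 sigma_scale = sigma_scale, max_ct = max_ct),
            class = "qpcr_noise_model")
}

#' Hybridization-counter noise model
#'
#' Probe counts for [simulate_hyb_runs()] are Poisson around
#' `background_mean + min(gain * abundance, saturation)`: an additive
#' non-specific background plus a linear response that clips at
#' `saturation`, compressing the usable dynamic range to roughly
#' `saturation / background_mean` (~10^3 with the defaults, as reported
#' for probe-hybridization counters).
#'
#' @param gain expected counts per abundance unit (> 0)
#' @param background_mean mean non-specific background count
#' @param saturation maximal expected specific count (> background_mean)
#' @return a `hyb_noise_model` list
#' @export
hyb_noise_model <- function(gain = 2, background_mean = 20, saturation = 2e4) {
  if (gain <= 0) stop_mirplat("gain must be positive")
  if (saturation <= background_mean)
    stop_mirplat("saturation must exceed background_mean")
  structure(list(gain = gain, background_mean = background_mean,
                 saturation = saturation), class = "hyb_noise_model")
}

#' Simulate replicate sequencing libraries
#'
#' Per run, the `round(depth * mirna_fraction)` miRNA-mapped reads are
#' allocated across miRNAs by a compound multinomial: the base
#' proportions (proportional to true abundance) are perturbed by
#' independent gamma factors with unit mean and squared CV `rho`, then
#' renormalized, and the reads drawn multinomially from the perturbed
#' composition. Each miRNA's across-replicate count then satisfies
#' `CV^2 ~= 1/mu + rho` (shot noise plus a uniform compositional-noise
#' floor), the closed form the LLOQ recovery oracle inverts. At
#' `rho = 0` the draw degenerates to a plain multinomial, whose column
#' sums equal the miRNA read total exactly.
#'
#' @param truth a [simulate_truth()] profile
#' @param model a [seq_noise_model()]
#' @param n_runs number of replicate libraries (>= 1)
#' @param seed integer seed
#' @return an [expr_matrix()] of raw counts (miRNA x run)
#' @export
simulate_seq_runs <- function(truth, model = seq_noise_model(), n_runs = 3L,
                              seed = 1L) {
  stopifnot(inherits(truth, "truth_profile"), inherits(model, "seq_noise_model"))
  if (n_runs < 1) stop_mirplat("n_runs must be >= 1")
  n_runs <- as.integer(n_runs)
  total <- round(model$depth * model$mirna_fraction)
  p <- truth$true_abundance / sum(truth$true_abundance)
  vals <- with_seed_or_current(seed, {
    sapply(seq_len(n_runs), function(r) {
      pr <- if (model$rho > 0) {
        w <- p * stats::rgamma(length(p), shape = 1 / model$rho,
                               scale = model$rho)
        w / sum(w)
      } else p
      as.numeric(stats::rmultinom(1L, size = total, prob = pr))
    })
  })
  vals <- matrix(vals, ncol = n_runs,
                 dimnames = list(truth$mirna_ids, sprintf("run%d", seq_len(n_runs))))
  expr_matrix(vals, scale = "counts")
}

#' Simulate replicate qPCR runs
#'
#' Expected copies per reaction are `true_abundance *
#' copies_per_reaction_scale`; the realized template number is Poisson,
#' and Ct follows the standard-curve line with Gaussian noise (see
#' [qpcr_noise_model()]). Cells with zero sampled molecules or
#' `Ct >= max_ct` are masked (not detected) — this module never emits a
#' numeric value past the censoring bound.
#'
#' @param truth a [simulate_truth()] profile
#' @param model a [qpcr_noise_model()]
#' @param copies_per_reaction_scale converts abundance units to expected
#'   copies per RT reaction (> 0)
#' @param n_runs number of replicate runs
#' @param seed integer seed
#' @return an [expr_matrix()] of raw Ct values with masked non-detections
#' @export
simulate_qpcr_runs <- function(truth, model = qpcr_noise_model(),
                               copies_per_reaction_scale = 1, n_runs = 3L,
                               seed = 1L) {
  stopifnot(inherits(truth, "truth_profile"), inherits(model, "qpcr_noise_model"))
  assert_scalar_number(copies_per_reaction_scale, "copies_per_reaction_scale",
                       positive = TRUE)
  if (n_runs < 1) stop_mirplat("n_runs must be >= 1")
  n_runs <- as.integer(n_runs)
  expected <- truth$true_abundance * copies_per_reaction_scale
  n <- length(expected)
  vals <- with_seed_or_current(seed, {
    sapply(seq_len(n_runs), function(r) {
      copies <- rpois_large(n, expected)
      sd_ct <- model$sigma0 + model$sigma_scale / sqrt(expected)
      ct <- model$intercept + model$slope * log10(pmax(copies, 1)) +
        stats::rnorm(n, 0, sd_ct)
      ct[copies == 0 | ct >= model$max_ct] <- NA_real_
      # numerical guard: the Ct axis starts at the first cycle
      pmax(ct, 1e-6)
    })
  })
  vals <- matrix(vals, ncol = n_runs,
                 dimnames = list(truth$mirna_ids, sprintf("run%d", seq_len(n_runs))))
  expr_matrix(vals, scale = "ct")
}

# rpois overflows its integer return above ~2e9 expected; fall back to the
# normal approximation there (relative error ~ 1/sqrt(lambda) < 3e-5)
rpois_large <- function(n, lambda) {
  big <- lambda > 1e9
  out <- numeric(n)
  if (any(!big)) out[!big] <- stats::rpois(sum(!big), lambda[!big])
  if (any(big)) out[big] <- round(stats::rnorm(sum(big), lambda[big], sqrt(lambda[big])))
  out
}

#' Simulate replicate hybridization-counter runs
#'
#' Endogenous probe counts are Poisson around background plus the
#' saturating linear response of [hyb_noise_model()]. Negative-control
#' probes draw pure background; positive-control probes draw at six
#' fixed graded levels spanning the instrument range. Control rows are
#' appended to the returned matrix so that [nanostring_normalize()] can
#' consume the output directly.
#'
#' @param truth a [simulate_truth()] profile
#' @param model a [hyb_noise_model()]
#' @param n_runs number of replicate runs
#' @param seed integer seed
#' @param n_neg_controls,n_pos_controls numbers of control probes (>= 1)
#' @return list with `matrix` (an [expr_matrix()] of counts including
#'   control rows), `neg_ids` and `pos_ids`
#' @export
simulate_hyb_runs <- function(truth, model = hyb_noise_model(), n_runs = 3L,
                              seed = 1L, n_neg_controls = 6L,
                              n_pos_controls = 6L) {
  stopifnot(inherits(truth, "truth_profile"), inherits(model, "hyb_noise_model"))
  if (n_runs < 1) stop_mirplat("n_runs must be >= 1")
  if (n_neg_controls < 1 || n_pos_controls < 1)
    stop_mirplat("control probe counts must be >= 1")
  n_runs <- as.integer(n_runs)
  neg_ids <- sprintf("NEG_%d", seq_len(n_neg_controls))
  pos_ids <- sprintf("POS_%d", seq_len(n_pos_controls))
  # graded positive levels: 4-fold ladder down from half of saturation
  pos_mu <- model$background_mean +
    model$saturation / 2 * 4^(-(seq_len(n_pos_controls) - 1L))
  endo_mu <- model$background_mean +
    pmin(model$gain * truth$true_abundance, model$saturation)
  vals <- with_seed_or_current(seed, {
    sapply(seq_len(n_runs), function(r) {
      c(stats::rpois(length(endo_mu), endo_mu),
        stats::rpois(length(neg_ids), model$background_mean),
        stats::rpois(length(pos_ids), pos_mu))
    })
  })
  ids <- c(truth$mirna_ids, neg_ids, pos_ids)
  vals <- matrix(vals, ncol = n_runs,
                 dimnames = list(ids, sprintf("run%d", seq_len(n_runs))))
  list(matrix = expr_matrix(vals, scale = "counts"),
       neg_ids = neg_ids, pos_ids = pos_ids)
}

#' Simulation presets
#'
#' Bundled parameter sets emulating two reference sample types:
#' * `"serum"` — biofluid-like: 6-log abundance span, 9% of reads mapping
#'   to miRNAs, overdispersion `rho = 0.125` (the Dirichlet-multinomial
#'   50%-CV crossing `1/(0.25 - rho)` then sits at 8 reads, the serum-like
#'   regime where the LLOQ rises above shot noise).
#' * `"brain"` — tissue-like: 38% miRNA-mapping fraction and `rho = 0`,
#'   the shot-noise-limited regime with a depth-stable LLOQ near 4 reads.
#'
#' @param name `"serum"` or `"brain"`
#' @return list with `truth_params` (`mu_log10`, `sigma_log10`,
#'   `n_mirnas`) and a [seq_noise_model()]
#' @export
simulation_preset <- function(name = c("serum", "brain")) {
  name <- match.arg(name)
  if (name == "serum") {
    list(name = "serum",
         truth_params = list(n_mirnas = 600L, mu_log10 = 2, sigma_log10 = 1),
         seq_model = seq_noise_model(depth = 2e7, rho = 0.125, mirna_fraction = 0.09))
  } else {
    list(name = "brain",
         truth_params = list(n_mirnas = 1200L, mu_log10 = 2, sigma_log10 = 1),
         seq_model = seq_noise_model(depth = 2e7, rho = 0, mirna_fraction = 0.38))
  }
}
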