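# mirplat

Cross-platform evaluation of circulating miRNA quantification.

Cell-free miRNAs in serum and plasma are promising non-invasive
biomarkers, but they sit near the sensitivity floor of every technology
used to measure them. Whether a candidate biomarker is usable depends on
a platform-level question: *which miRNAs does this platform quantify
reliably, at what abundance, and how reproducibly?* `mirplat` implements
the evaluation toolkit for that question on technical replicate runs of
qPCR panels, hybridization counters (nCounter-style) and small-RNA
sequencing:

* **LLOQ estimation** — per-miRNA replicate statistics
  (CV = s/x̄, n−1 denominator), a degree-1 LOESS trend of CV against
  log10 mean expression, and the lower limit of quantification as the
  abundance where the trend crosses 50% CV from above:
  `compute_replicate_stats()`, `fit_cv_trend()`, `estimate_lloq()`,
  `classify_above_lloq()`, or `lloq_pipeline()` for the whole chain.
* **Reproducibility** — Lin's concordance correlation coefficient
  ccc = 2·s_xy / (s_x² + s_y² + (x̄ − ȳ)²) averaged over run pairs
  (`lin_ccc()`, `pairwise_run_concordance()`), and Spearman rank
  correlation between platforms with Ct-orientation handling
  (`spearman_platform_correlation()`).
* **Depth saturation** — without-replacement (hypergeometric) read
  subsampling, detection-rate and LLOQ-versus-depth curves, and a
  saturation-depth summary: `subsample_counts()`, `detection_curve()`,
  `lloq_vs_depth()`, `saturation_depth()`.
* **Normalization** — qPCR standard-curve absolute quantification
  (`fit_standard_curve()`, `ct_to_copies()`,
  `copies_to_concentration()`), residual-Ct spike-in normalization
  (`spikein_normalize_ct()`), three-step hybridization-count
  normalization (`nanostring_normalize()`), and reads-per-million
  (`rpm_normalize()`).
* **Cross-platform comparison** — overlap membership patterns of
  quantifiable sets, panel-content accounting separating panel gaps from
  sensitivity gaps, and a deterministic comparison report:
  `overlap_analysis()`, `panel_accounting()`, `comparison_report()`.
* **Synthetic multi-platform data** — a generator producing sequencing,
  qPCR and hybridization measurements from one shared log-normal ground
  truth, with closed-form noise structure (sequencing replicate
  CV² ≈ 1/μ + ρ) so every estimator has an analytic recovery target:
  `simulate_truth()`, `simulate_seq_runs()`, `simulate_qpcr_runs()`,
  `simulate_hyb_runs()`, `simulation_preset()`.

Expression data live in a dense `expr_matrix` (miRNA × run) with a
declared scale (`ct`, `counts`, `copies`, `copies_per_ml`, `rpm`,
`normalized_counts`) and explicit not-detected masking — a zero read
count is an observed value, and masking happens only through a
platform's limit-of-detection rule (`apply_lod()`: counts ≥ 5 pass,
Ct < 40 passes).

## Worked example

Simulate four replicate serum-like sequencing libraries (20M reads, 9%
miRNA-mapped, compositional overdispersion ρ = 0.125) and estimate the
platform's LLOQ and reproducibility:

```r
library(mirplat)

truth <- simulate_truth(n_mirnas = 600, mu_log10 = 2, sigma_log10 = 1,
                        seed = 42)
runs <- simulate_seq_runs(truth,
                          seq_noise_model(depth = 2e7, rho = 0.125,
                                          mirna_fraction = 0.09),
                          n_runs = 4, seed = 43)
runs
#> expr_matrix: 600 miRNAs x 4 runs, scale = counts, 0 not-detected cell(s)

res <- lloq_pipeline(runs, min_runs = 3)
res
#> lloq_result: flag = interior_crossing, cutoff = 50% CV, LLOQ = 8.696
length(res$above_lloq)
#> [1] 554

cc <- pairwise_run_concordance(rpm_normalize(runs))
cc
#> concordance_result: 4 runs, average pairwise ccc = 0.962
```

The LLOQ of 8.7 reads recovers the analytic 50%-CV crossing of this
noise model, 1/(0.25 − ρ) = 8 reads: miRNAs with fewer than ~9 mapped
reads per library cannot be measured at better than 50% CV on this
simulated platform, and 554 of the 600 miRNAs sit above that limit. The
average pairwise ccc of 0.96 summarizes inter-run reproducibility on the
log10 RPM scale.

The full multi-platform pipeline (three technologies from one ground
truth, normalization, LLOQ, concordance, saturation and the comparison
report, with a manifest of MD5-checksummed artifacts) runs from a single
config:

```r
cfg <- read_pipeline_config(system.file("extdata", "demo_config.yaml",
                                        package = "mirplat"))
res <- run_pipeline(cfg, "mirplat-demo")
res$report
```

See the vignette (`vignettes/platform-evaluation.Rmd`) for the methods,
the generator's noise models and their limits, and all numerical
choices.

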