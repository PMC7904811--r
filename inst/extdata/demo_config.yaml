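# demo configuration for run_pipeline(): three synthetic platforms
# (sequencing, qPCR, hybridization counter) from one shared ground truth
seed: 7
n_mirnas: 400
mu_log10: 2
sigma_log10: 1
n_runs: 4
cutoff: 0.5
span: 0.75
min_runs: 3
lod: 5
n_resamples: 8
seq_model:
  depth: 1000000
  rho: 0.125
  mirna_fraction: 0.09
qpcr_model:
  slope: -3.32
  intercept: 38
  sigma0: 0.1
  sigma_scale: 0.5
  max_ct: 40
hyb_model:
  gain: 2
  background_mean: 20
  saturation: 20000
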