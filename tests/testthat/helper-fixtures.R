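# small fixture builders shared across test files

`%||%` <- function(a, b) if (is.null(a)) b else a

# counts matrix from a plain numeric matrix (row-major literal)
counts_mat <- function(..., nrow, ids = NULL, runs = NULL, scale = "counts") {
  m <- matrix(c(...), nrow = nrow, byrow = TRUE)
  rownames(m) <- ids %||% sprintf("mir-%d", seq_len(nrow(m)))
  colnames(m) <- runs %||% sprintf("run%d", seq_len(ncol(m)))
  expr_matrix(m, scale = scale)
}

# random expression matrix for round-trip properties
random_matrix <- function(seed, n = 8, k = 4, scale = "rpm") {
  withr::with_seed(seed, {
    v <- matrix(stats::runif(n * k) * 10^stats::runif(n * k, 0, 5), n, k)
    v[stats::runif(n * k) < 0.2] <- NA
    dimnames(v) <- list(sprintf("hsa-miR-%d-5p", seq_len(n)),
                        sprintf("run%d", seq_len(k)))
    expr_matrix(v, scale = scale)
  })
}

# replicate runs with known Poisson/overdispersed structure, small scale
sim_small_seq <- function(seed, rho = 0, n_mirnas = 400, depth = 2e5,
                          n_runs = 4) {
  truth <- simulate_truth(n_mirnas, mu_log10 = 2, sigma_log10 = 1, seed = seed)
  simulate_seq_runs(truth,
                    seq_noise_model(depth = depth, rho = rho,
                                    mirna_fraction = 0.5),
                    n_runs = n_runs, seed = seed + 1000L)
}
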