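# shared fixtures: small designs and reduced sampler settings used across tests

test_Q <- function() {
  rate_matrix(c(SF = 0.5, SB = 0.1, FS = 1.2, FB = 0.1, BS = 1.4, BF = 0.8))
}

# random symmetric PSD matrix (A'A construction)
random_psd <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rnorm(n * n), n)
  crossprod(A) / n
}

# small phenotype design for quick multivariate fits
quick_design <- function(n_lines = 40, ...) {
  simulation_design(n_lines = n_lines, n_blocks = 8, plates_per_line = 2, ...)
}

quick_mcmc <- function(table, ...) {
  fit_mmatrix_model(table, n_iter = 3000, burnin = 600, thin = 4, ...)
}
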