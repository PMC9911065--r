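#' Bayesian multivariate mixed model for trait (co)variance matrices
#'
#' Fits the six log transition rates as a multivariate response
#'
#'   `y_i = mu + beta_T T + beta_H H + beta_D D (+ extra fixed) + line + block + e`
#'
#' by Gibbs sampling: multivariate-normal full conditionals for the fixed
#' effects and the line/block effect vectors, inverse-Wishart full
#' conditionals for the line, block and residual covariance matrices. The
#' prior on each covariance matrix is inverse-Wishart with degrees of freedom
#' `prior_nu` (default: number of traits + 1, the weakest proper choice) and
#' scale the diagonal matrix of empirical phenotypic variances. Covariates
#' are mean-centered before fitting so the intercepts are trait means.
#'
#' The study-scale settings are 500,000 iterations, 50,000 burn-in and
#' thinning 10; reduced settings are appropriate for simulation checks.
#'
#' @param table phenotype table (see [simulate_phenotypes()] for the layout).
#' @param traits trait column names (default `ln_SF` ... `ln_BF`).
#' @param covariates numeric covariate columns entering as fixed effects.
#' @param extra_fixed optional factor column added as a fixed effect (e.g.
#'   assay year for a standing-variation G-matrix fit).
#' @param n_iter,burnin,thin MCMC settings.
#' @param prior_nu inverse-Wishart prior degrees of freedom.
#' @param prior_scale prior scale matrix; default `diag(phenotypic variances)`.
#' @param v_beta prior variance of each fixed-effect coefficient.
#' @param seed optional integer seed; when supplied the sample stream is
#'   fully reproducible.
#' @return a `matrix_posterior` object: arrays `line`, `block`, `residual`
#'   (d x d x draws), `beta` (p x d x draws), trait names, settings, and
#'   `autocorrelation` diagnostics (max lag-1 autocorrelation over stored
#'   line-covariance elements, plus a flag against the 0.05 threshold).
#' @export
fit_mmatrix_model <- function(table,
                              traits = paste0("ln_", TRAITS),
                              covariates = c("temperature", "humidity", "logdens"),
                              extra_fixed = NULL,
                              n_iter = 500000, burnin = 50000, thin = 10,
                              prior_nu = NULL, prior_scale = NULL,
                              v_beta = 1e8, seed = NULL) {
  if (!all(traits %in% names(table)))
    stop("missing trait column(s): ",
         paste(setdiff(traits, names(table)), collapse = ", "))
  Y <- as.matrix(table[, traits])
  if (anyNA(Y)) stop("missing trait values are not supported; drop those rows")
  d <- ncol(Y)
  n_line <- length(unique(table$line_id))
  if (n_line < 5) stop("need at least 5 lines")

  Xparts <- list(intercept = rep(1, nrow(Y)))
  for (cv in covariates) {
    if (!cv %in% names(table)) stop("missing covariate column: ", cv)
    Xparts[[cv]] <- table[[cv]] - mean(table[[cv]])
  }
  X <- do.call(cbind, Xparts)
  if (!is.null(extra_fixed)) {
    f <- factor(table[[extra_fixed]])
    if (nlevels(f) > 1) {
      D <- model.matrix(~f)[, -1, drop = FALSE]
      colnames(D) <- paste0(extra_fixed, levels(f)[-1])
      X <- cbind(X, D)
    }
  }

  if (is.null(prior_nu)) prior_nu <- d + 1
  if (prior_nu <= d - 1) stop("prior_nu must exceed n_traits - 1")
  if (is.null(prior_scale)) prior_scale <- diag(apply(Y, 2, var), d)
  ev <- eigen(prior_scale, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("prior scale must be positive definite")

  line <- as.integer(factor(table$line_id)) - 1L
  block <- as.integer(factor(table$block_id)) - 1L

  if (!is.null(seed)) set.seed(seed)
  res <- .gibbs_mmm(Y, X, line, block,
                    n_lines = max(line) + 1L, n_blocks = max(block) + 1L,
                    nu0 = prior_nu, S0 = prior_scale, v_beta = v_beta,
                    n_iter = as.integer(n_iter), burnin = as.integer(burnin),
                    thin = as.integer(thin))

  dimnames(res$line) <- dimnames(res$block) <- dimnames(res$residual) <-
    list(traits, traits, NULL)
  dimnames(res$beta) <- list(colnames(X), traits, NULL)

  ac <- chain_autocorrelation(res$line)
  structure(list(line = res$line, block = res$block, residual = res$residual,
                 beta = res$beta, traits = traits,
                 settings = list(n_iter = n_iter, burnin = burnin, thin = thin,
                                 prior_nu = prior_nu,
                                 prior_scale = prior_scale),
                 autocorrelation = ac),
            class = "matrix_posterior")
}

#' Lag-1 autocorrelation diagnostic of a stored matrix chain
#'
#' Computes the autocorrelation at the thinned lag for every distinct matrix
#' element's chain and compares the maximum against the 0.05 convergence
#' threshold used to vet the study-scale chains.
#'
#' @param samples d x d x draws array.
#' @param threshold flag level.
#' @return list with `max_lag1`, `flagged`, `per_element` matrix.
#' @export
chain_autocorrelation <- function(samples, threshold = 0.05) {
  d <- dim(samples)[1]
  per <- matrix(NA_real_, d, d, dimnames = dimnames(samples)[1:2])
  for (i in seq_len(d)) for (j in seq(i, d)) {
    x <- samples[i, j, ]
    if (sd(x) == 0) { per[i, j] <- per[j, i] <- 0; next }
    a <- acf(x, lag.max = 1, plot = FALSE)$acf[2]
    per[i, j] <- per[j, i] <- a
  }
  mx <- max(abs(per))
  list(max_lag1 = mx, flagged = mx > threshold, per_element = per)
}

#' Mutational covariance matrix from a model posterior
#'
#' M is half the among-line covariance matrix: MA lines are fully homozygous,
#' so the line variance is twice the per-generation mutational input scale.
#'
#' @param posterior a `matrix_posterior` from [fit_mmatrix_model()].
#' @return an `m_posterior` list: `samples` (d x d x draws of M),
#'   `mean` (posterior-mean M), `traits`.
#' @export
m_matrix <- function(posterior) {
  stopifnot(inherits(posterior, "matrix_posterior"))
  samples <- posterior$line * 0.5
  structure(list(samples = samples,
                 mean = apply(samples, c(1, 2), mean),
                 traits = posterior$traits),
            class = "m_posterior")
}

#' Posterior mean of a sample array
#' @param x `m_posterior`, `matrix_posterior` (line component) or array.
#' @export
posterior_mean <- function(x) {
  if (inherits(x, "m_posterior")) return(x$mean)
  apply(posterior_array(x), c(1, 2), mean)
}

#' Element-wise equal-tailed credible intervals of a matrix posterior
#' @param x matrix sample set (array or posterior object).
#' @param level interval mass.
#' @return list of `lower` and `upper` matrices.
#' @export
posterior_ci_matrix <- function(x, level = 0.95) {
  arr <- posterior_array(x)
  a <- (1 - level) / 2
  list(lower = apply(arr, c(1, 2), quantile, probs = a),
       upper = apply(arr, c(1, 2), quantile, probs = 1 - a))
}

#' Permutation-null M matrices
#'
#' Shuffles line and block identities independently across rows, refits the
#' multivariate model, and stores the posterior-mean M of each replicate.
#' The collection provides null credible bands for any statistic of M
#' (element values, trace, rotated eigenvalues, tensor eigenvalues).
#'
#' @param table phenotype table.
#' @param n_rand number of permutation replicates (study scale: 1000).
#' @param n_iter,burnin,thin reduced MCMC settings per refit.
#' @param seed optional seed governing permutations and refits.
#' @param ... passed to [fit_mmatrix_model()].
#' @return a `null_m_set` list: `samples` (d x d x n_rand array of
#'   posterior-mean null Ms), `trace` (length-n_rand vector).
#' @export
randomized_null_m <- function(table, n_rand = 1000,
                              n_iter = 5000, burnin = 1000, thin = 4,
                              seed = NULL, ...) {
  if (n_rand < 1) stop("n_rand must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  d <- 6
  first <- NULL
  samples <- NULL
  tr <- numeric(n_rand)
  for (r in seq_len(n_rand)) {
    perm <- table
    perm$line_id <- sample(perm$line_id)
    perm$block_id <- sample(perm$block_id)
    fit <- fit_mmatrix_model(perm, n_iter = n_iter, burnin = burnin,
                             thin = thin, ...)
    Mbar <- m_matrix(fit)$mean
    if (is.null(samples))
      samples <- array(NA_real_, c(nrow(Mbar), ncol(Mbar), n_rand),
                       dimnames = list(rownames(Mbar), colnames(Mbar), NULL))
    samples[, , r] <- Mbar
    tr[r] <- sum(diag(Mbar))
  }
  structure(list(samples = samples, trace = tr), class = "null_m_set")
}

#' Draw from the inverse-Wishart distribution
#'
#' Parameterized so that the density is proportional to
#' `|X|^-((df + d + 1)/2) exp(-tr(S X^-1)/2)`, with mean `S / (df - d - 1)`
#' for `df > d + 1`.
#'
#' @param df degrees of freedom (> d - 1).
#' @param S positive-definite scale matrix.
#' @return one d x d draw.
#' @export
rinvwishart <- function(df, S) {
  .rinvwishart(df, as.matrix(S))
}
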