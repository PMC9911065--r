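#' Build a continuous-time Markov chain rate matrix from six transition rates
#'
#' Movement states are still (S), forward (F) and backward (B). The six free
#' parameters are the off-diagonal instantaneous rates (per second); each
#' diagonal entry is constrained to minus the sum of the off-diagonal rates of
#' its row, so that rows sum to zero and `expm(Q * dt)` is row-stochastic.
#'
#' @param rates named numeric vector with elements `SF`, `SB`, `FS`, `FB`,
#'   `BS`, `BF`: the rate of switching from the first state of the name to the
#'   second, in transitions per second. All must be >= 0.
#' @return a 3x3 `rate_matrix` with dimnames `S`, `F`, `B`.
#' @examples
#' Q <- rate_matrix(c(SF = 0.5, SB = 0.1, FS = 1.2, FB = 0.1, BS = 1.4, BF = 0.8))
#' rowSums(Q)  # all zero
#' @export
rate_matrix <- function(rates) {
  if (is.matrix(rates)) {
    validate_rate_matrix(rates)
    return(structure(rates, class = c("rate_matrix", class(rates))))
  }
  if (!all(TRAITS %in% names(rates)))
    stop("`rates` must be named with all of: ", paste(TRAITS, collapse = ", "))
  if (any(rates < 0)) stop("transition rates must be non-negative")
  q <- matrix(0, 3, 3, dimnames = list(STATES, STATES))
  for (nm in TRAITS) {
    from <- substr(nm, 1, 1); to <- substr(nm, 2, 2)
    q[from, to] <- unname(rates[[nm]])
  }
  diag(q) <- -rowSums(q)
  structure(q, class = c("rate_matrix", "matrix", "array"))
}

validate_rate_matrix <- function(Q, tol = 1e-12) {
  if (!is.matrix(Q) || nrow(Q) != ncol(Q))
    stop("Q must be a square matrix")
  off <- Q; diag(off) <- 0
  if (any(off < 0))
    stop("rate matrix structure violation: negative off-diagonal entry")
  if (any(abs(rowSums(Q)) > tol * max(1, max(abs(Q)))))
    stop("rate matrix structure violation: rows must sum to zero")
  invisible(Q)
}

#' Extract the six off-diagonal rates in canonical (SF, SB, FS, FB, BS, BF) order
#' @param Q a 3x3 rate matrix with S/F/B dimnames.
#' @return named numeric vector of length 6.
#' @export
rates_from_matrix <- function(Q) {
  vapply(TRAITS, function(nm)
    Q[substr(nm, 1, 1), substr(nm, 2, 2)], numeric(1))
}

#' Stationary distribution of a rate matrix
#'
#' Solves pi Q = 0 subject to sum(pi) = 1 by least squares on the augmented
#' system.
#'
#' @param Q a valid rate matrix.
#' @return named probability vector over the states.
#' @export
stationary_distribution <- function(Q) {
  validate_rate_matrix(Q)
  k <- nrow(Q)
  A <- rbind(t(Q), rep(1, k))
  b <- c(rep(0, k), 1)
  p <- qr.solve(A, b)
  names(p) <- rownames(Q)
  p
}

#' Tally observed one-frame transitions from state sequences
#'
#' The 3x3 table of consecutive-frame state pairs is the sufficient statistic
#' for the discretely observed chain.
#'
#' @param sequences a single character vector of states, or a list of them
#'   (one per tracked object). Allowed labels: S, F, B.
#' @param dt frame interval in seconds shared by all sequences.
#' @return a `transition_counts` object: list with integer matrix `n` and `dt`.
#' @export
count_transitions <- function(sequences, dt) {
  if (is.character(sequences)) sequences <- list(sequences)
  if (length(sequences) == 0) stop("no state sequences supplied")
  if (length(dt) != 1 || dt <= 0) stop("`dt` must be a single positive number")
  n <- matrix(0L, 3, 3, dimnames = list(STATES, STATES))
  for (s in sequences) {
    s <- as.character(s)
    if (!all(s %in% STATES))
      stop("unknown state label: ", paste(unique(setdiff(s, STATES)), collapse = ", "))
    if (length(s) < 2) next
    from <- factor(s[-length(s)], levels = STATES)
    to <- factor(s[-1], levels = STATES)
    n <- n + table(from, to)
  }
  storage.mode(n) <- "integer"
  dimnames(n) <- list(STATES, STATES)
  structure(list(n = n, dt = dt), class = "transition_counts")
}

#' Transition probability matrix over one observation interval
#'
#' Computes the matrix exponential `expm(Q * dt)`, the probability of observing
#' state j at the next frame given state i now.
#'
#' @param Q a valid rate matrix.
#' @param dt interval in seconds.
#' @return 3x3 row-stochastic matrix.
#' @export
transition_probability <- function(Q, dt) {
  validate_rate_matrix(Q)
  P <- as.matrix(Matrix::expm(Matrix::Matrix(unclass(Q) * dt)))
  dimnames(P) <- dimnames(Q)
  # clip matrix-exponential roundoff
  P[P < 0] <- 0
  P[P > 1] <- 1
  P
}

#' Log-likelihood of transition counts under a rate matrix
#'
#' `sum(n_ij * log(P_ij(dt)))` with `P = expm(Q dt)`; returns `-Inf` when a
#' transition with zero probability was observed.
#'
#' @param Q a valid rate matrix.
#' @param counts a `transition_counts` object.
#' @return scalar log-likelihood.
#' @export
ctmc_loglik <- function(Q, counts) {
  stopifnot(inherits(counts, "transition_counts"))
  P <- transition_probability(Q, counts$dt)
  n <- counts$n
  if (any(n > 0 & P <= 0)) return(-Inf)
  sum(n[n > 0] * log(P[n > 0]))
}

#' Maximum-likelihood estimation of the six transition rates
#'
#' Maximizes the discretely observed chain likelihood over the six log rates
#' (box-constrained quasi-Newton in log space, which keeps every rate
#' positive); the diagonal is reconstructed from the row-sum-zero constraint.
#' Rates leaving a state never observed as a source are unidentifiable: they
#' are fixed at `rate_floor` and flagged, never silently dropped. Rates pushed
#' to the lower box bound (e.g. when no departure from a state was ever seen)
#' are likewise floored and flagged.
#'
#' @param counts a `transition_counts` object with at least one observed pair.
#' @param init optional initial rate matrix; defaults to the naive estimator
#'   `n_ij / (n_i. * dt)` (exact in the small-`dt` limit).
#' @param rate_floor lower bound for a rate, per second.
#' @param rate_ceiling upper bound for a rate, per second.
#' @return a `rate_fit` list: `Q` (fitted `rate_matrix`), `rates` (canonical
#'   6-vector), `loglik`, `converged`, `flags` (per-rate character flags,
#'   `"ok"`, `"floored"` or `"unidentifiable"`).
#' @export
fit_rates <- function(counts, init = NULL, rate_floor = 1e-8,
                      rate_ceiling = 1e3) {
  stopifnot(inherits(counts, "transition_counts"))
  n <- counts$n; dt <- counts$dt
  if (sum(n) < 1) stop("need at least one observed transition pair")

  out_tot <- rowSums(n)
  seen <- out_tot > 0
  naive <- naive_rates(counts, floor = rate_floor)
  if (is.null(init)) init <- rate_matrix(naive)
  init_rates <- pmin(pmax(rates_from_matrix(init), rate_floor), rate_ceiling)

  src <- substr(TRAITS, 1, 1)
  free <- seen[src]                       # rates with an observed source state
  theta0 <- log(init_rates)

  negll <- function(theta_free) {
    th <- theta0
    th[free] <- theta_free
    Q <- rate_matrix(exp(th))
    -ctmc_loglik(Q, counts)
  }

  flags <- setNames(rep("ok", 6), TRAITS)
  flags[!free] <- "unidentifiable"

  if (any(free)) {
    opt <- optim(theta0[free], negll, method = "L-BFGS-B",
                 lower = log(rate_floor), upper = log(rate_ceiling),
                 control = list(maxit = 500))
    theta <- theta0
    theta[free] <- opt$par
    converged <- opt$convergence == 0
  } else {
    theta <- theta0
    converged <- TRUE
  }
  rates <- exp(theta)
  rates[!free] <- rate_floor
  at_floor <- free & rates <= rate_floor * (1 + 1e-6)
  flags[at_floor] <- "floored"
  rates[at_floor] <- rate_floor

  Q <- rate_matrix(rates)
  ll <- ctmc_loglik(Q, counts)
  # the optimizer starts at the naive estimator, so this can only improve
  init_ll <- ctmc_loglik(rate_matrix(init_rates), counts)
  if (is.finite(init_ll) && ll < init_ll - 1e-8) {
    Q <- rate_matrix(init_rates)
    ll <- init_ll
    converged <- FALSE
  }
  structure(list(Q = Q, rates = rates_from_matrix(Q), loglik = ll,
                 converged = converged, flags = flags, dt = dt),
            class = "rate_fit")
}

naive_rates <- function(counts, floor = 1e-8) {
  n <- counts$n
  out_tot <- rowSums(n)
  r <- vapply(TRAITS, function(nm) {
    from <- substr(nm, 1, 1); to <- substr(nm, 2, 2)
    if (out_tot[from] == 0) return(floor)
    max(n[from, to] / (out_tot[from] * counts$dt), floor)
  }, numeric(1))
  r
}

#' Random-walk Metropolis sampler over log transition rates
#'
#' Optional Bayesian counterpart of [fit_rates()]: independent normal priors
#' on the six log rates (mean 0, sd 10 by default, effectively flat over the
#' plausible range), Gaussian random-walk proposals. With the data volumes of
#' a typical tracking movie the posterior mean is indistinguishable from the
#' MLE; the sampler exists to check that equivalence.
#'
#' @param counts a `transition_counts` object.
#' @param n_iter,burnin,proposal_sd sampler settings.
#' @param prior_sd sd of the normal prior on each log rate.
#' @param init optional starting `rate_matrix` (default: naive estimator).
#' @return list with `samples` (iterations x 6 matrix of log rates),
#'   `posterior_mean_rates` (6-vector, natural scale), `accept_rate`.
#' @export
sample_rates_posterior <- function(counts, n_iter = 2000, burnin = 500,
                                   proposal_sd = 0.05, prior_sd = 10,
                                   init = NULL) {
  stopifnot(inherits(counts, "transition_counts"))
  theta <- log(if (is.null(init)) naive_rates(counts) else rates_from_matrix(init))
  lp <- function(th) {
    ll <- ctmc_loglik(rate_matrix(exp(th)), counts)
    ll + sum(dnorm_log(th, 0, prior_sd))
  }
  cur <- lp(theta)
  keep <- matrix(NA_real_, n_iter - burnin, 6,
                 dimnames = list(NULL, TRAITS))
  acc <- 0L
  for (it in seq_len(n_iter)) {
    prop <- theta + rnorm(6, 0, proposal_sd)
    cand <- lp(prop)
    if (is.finite(cand) && log(runif(1)) < cand - cur) {
      theta <- prop; cur <- cand; acc <- acc + 1L
    }
    if (it > burnin) keep[it - burnin, ] <- theta
  }
  list(samples = keep,
       posterior_mean_rates = colMeans(exp(keep)),
       accept_rate = acc / n_iter)
}

dnorm_log <- function(x, mean, sd) -0.5 * log(2 * pi) - log(sd) - (x - mean)^2 / (2 * sd^2)

#' Per-plate log transition rates
#'
#' Fits the six rates from all state sequences of one plate and returns their
#' natural logarithms in canonical (SF, SB, FS, FB, BS, BF) order — the trait
#' vector all downstream (co)variance models consume.
#'
#' @param sequences list of state-label vectors for the plate.
#' @param dt frame interval in seconds.
#' @param ... passed to [fit_rates()].
#' @return named numeric 6-vector of log rates, with attributes `flags` and
#'   `converged` propagated from the fit.
#' @export
summarize_plate_rates <- function(sequences, dt, ...) {
  counts <- count_transitions(sequences, dt)
  fit <- fit_rates(counts, ...)
  out <- log(fit$rates)
  names(out) <- TRAITS
  attr(out, "flags") <- fit$flags
  attr(out, "converged") <- fit$converged
  out
}
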