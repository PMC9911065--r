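test_that("rate matrix construction enforces the generator constraints", {
  Q <- test_Q()
  expect_equal(unname(rowSums(Q)), rep(0, 3), tolerance = 1e-12)
  expect_true(all(Q[row(Q) != col(Q)] >= 0))
  expect_error(rate_matrix(c(SF = -1, SB = 1, FS = 1, FB = 1, BS = 1, BF = 1)),
               "non-negative")
  bad <- unclass(test_Q()); bad[1, 1] <- 0
  expect_error(rate_matrix(bad), "sum to zero")
  bad2 <- unclass(test_Q()); bad2[1, 2] <- -bad2[1, 2]
  expect_error(rate_matrix(bad2), "negative off-diagonal")
  # labeling contract: rates_from_matrix inverts construction
  r <- c(SF = .1, SB = .2, FS = .3, FB = .4, BS = .5, BF = .6)
  expect_equal(rates_from_matrix(rate_matrix(r)), r)
})

test_that("transition counting enumerates consecutive-frame pairs", {
  cnt <- count_transitions(list(c("S", "S", "F")), dt = 0.25)
  expected <- matrix(0L, 3, 3, dimnames = list(c("S","F","B"), c("S","F","B")))
  expected["S", "S"] <- 1L; expected["S", "F"] <- 1L
  expect_equal(cnt$n, expected)

  # additivity over replicated sequences
  k <- 5
  cnt_k <- count_transitions(rep(list(c("S", "S", "F")), k), dt = 0.25)
  expect_equal(cnt_k$n, expected * k)

  expect_error(count_transitions(list(), dt = 0.25), "no state sequences")
  expect_error(count_transitions(list(c("S", "X")), dt = 0.25), "unknown state")
})

test_that("transition probabilities are a proper stochastic kernel", {
  Q0 <- rate_matrix(c(SF = 0, SB = 0, FS = 0, FB = 0, BS = 0, BF = 0))
  expect_equal(transition_probability(Q0, 1), diag(3),
               ignore_attr = TRUE, tolerance = 1e-12)

  Q <- test_Q()
  P <- transition_probability(Q, 0.25)
  expect_equal(unname(rowSums(P)), rep(1, 3), tolerance = 1e-10)
  expect_true(all(P >= 0 & P <= 1))

  # first-order Taylor agreement at tiny dt
  dt <- 1e-6
  P_small <- transition_probability(Q, dt)
  expect_equal(P_small, diag(3) + unclass(Q) * dt,
               ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("log-likelihood matches a brute-force per-pair sum and is linear in counts", {
  set.seed(11)
  cd <- ctmc_design(Q = test_Q(), duration = 120, frame_rate = 4, n_objects = 3)
  df <- simulate_state_sequences(cd)
  seqs <- state_sequence_list(df)
  cnt <- count_transitions(seqs, dt = 0.25)
  Q <- rate_matrix(c(SF = .4, SB = .2, FS = 1, FB = .2, BS = 1, BF = .6))

  # oracle: loop over consecutive pairs without aggregation
  P <- transition_probability(Q, 0.25)
  ll_brute <- 0
  for (s in seqs)
    for (i in seq_len(length(s) - 1))
      ll_brute <- ll_brute + log(P[s[i], s[i + 1]])
  expect_equal(ctmc_loglik(Q, cnt), ll_brute, tolerance = 1e-10)

  # linearity in counts
  cnt2 <- cnt; cnt2$n <- cnt$n * 2L
  expect_equal(ctmc_loglik(Q, cnt2), 2 * ctmc_loglik(Q, cnt), tolerance = 1e-10)

  # all-diagonal counts under Q = 0: every observed pair has probability 1
  Q0 <- rate_matrix(setNames(rep(0, 6), c("SF","SB","FS","FB","BS","BF")))
  diag_cnt <- cnt; diag_cnt$n[,] <- 0L; diag(diag_cnt$n) <- c(5L, 3L, 2L)
  expect_equal(ctmc_loglik(Q0, diag_cnt), 0)
  # but off-diagonal observations are impossible under Q = 0
  expect_equal(ctmc_loglik(Q0, cnt), -Inf)
})

test_that("MLE recovers generating rates and agrees with the naive estimator at high frame rate", {
  set.seed(21)
  Q <- test_Q()
  # long enough that even the rare 0.1/s rates collect >1000 observed
  # transitions (Monte Carlo SE ~3%, safely inside the 10% bound)
  cd <- ctmc_design(Q = Q, duration = 60000, frame_rate = 4, n_objects = 1)
  cnt <- count_transitions(state_sequence_list(simulate_state_sequences(cd)),
                           dt = 0.25)
  fit <- fit_rates(cnt)
  expect_true(fit$converged)
  expect_true(all(fit$flags == "ok"))
  relerr <- abs(fit$rates - rates_from_matrix(Q)) / rates_from_matrix(Q)
  expect_lt(max(relerr), 0.10)
  # Eq.-2 constraint on the fitted matrix, to numerical precision
  expect_equal(unname(rowSums(fit$Q)), rep(0, 3), tolerance = 1e-12)
  # fitted likelihood can only improve on the naive initializer
  naive <- rate_matrix(mutcov:::naive_rates(cnt))
  expect_gte(fit$loglik, ctmc_loglik(naive, cnt))

  # small-dt regime: MLE and naive estimator coincide (their relative
  # difference scales with exit-rate x dt, so dt must be small against the
  # fastest exit rate of ~2.2/s)
  set.seed(22)
  cd_fast <- ctmc_design(Q = Q, duration = 400, frame_rate = 250, n_objects = 1)
  cnt_fast <- count_transitions(state_sequence_list(simulate_state_sequences(cd_fast)),
                                dt = 0.004)
  fit_fast <- fit_rates(cnt_fast)
  naive_fast <- mutcov:::naive_rates(cnt_fast)
  seen <- cnt_fast$n[cbind(substr(names(naive_fast), 1, 1),
                           substr(names(naive_fast), 2, 2))] > 0
  expect_lt(max(abs(fit_fast$rates[seen] - naive_fast[seen]) /
                  naive_fast[seen]), 0.01)
})

test_that("unidentifiable and boundary rates are floored and flagged", {
  # all mass on the diagonal: no departure ever observed
  n <- matrix(0L, 3, 3, dimnames = list(c("S","F","B"), c("S","F","B")))
  diag(n) <- c(50L, 50L, 50L)
  cnt <- structure(list(n = n, dt = 0.25), class = "transition_counts")
  fit <- fit_rates(cnt)
  expect_true(all(fit$rates == 1e-8))
  expect_true(all(fit$flags %in% c("floored", "unidentifiable")))

  # state B never observed as a source
  n2 <- n; n2["B", "B"] <- 0L; n2["S", "F"] <- 10L
  cnt2 <- structure(list(n = n2, dt = 0.25), class = "transition_counts")
  fit2 <- fit_rates(cnt2)
  expect_equal(unname(fit2$flags[c("BS", "BF")]),
               c("unidentifiable", "unidentifiable"))
  expect_equal(unname(fit2$rates[c("BS", "BF")]), c(1e-8, 1e-8))
})

test_that("plate summaries return ordered log rates", {
  # unit rates -> log vector of zeros (fit on counts from the exact kernel
  # would still be noisy, so check the labeling/ordering contract directly)
  set.seed(31)
  Q <- test_Q()
  cd <- ctmc_design(Q = Q, duration = 2500, frame_rate = 4, n_objects = 2)
  df <- simulate_state_sequences(cd)
  lr <- summarize_plate_rates(state_sequence_list(df), dt = 0.25)
  expect_equal(names(lr), c("SF", "SB", "FS", "FB", "BS", "BF"))
  # element 3 is ln q(F -> S)
  cnt <- count_transitions(state_sequence_list(df), dt = 0.25)
  fit <- fit_rates(cnt)
  expect_equal(unname(lr[3]), unname(log(fit$Q["F", "S"])))
  expect_true(attr(lr, "converged"))
})

test_that("the Metropolis sampler's posterior mean matches the MLE on large counts", {
  set.seed(41)
  Q <- test_Q()
  cd <- ctmc_design(Q = Q, duration = 2500, frame_rate = 4, n_objects = 1)
  cnt <- count_transitions(state_sequence_list(simulate_state_sequences(cd)),
                           dt = 0.25)
  mle <- fit_rates(cnt)
  post <- sample_rates_posterior(cnt, n_iter = 3000, burnin = 1000)
  expect_gt(post$accept_rate, 0.05)
  expect_lt(max(abs(post$posterior_mean_rates - mle$rates) / mle$rates), 0.15)
})
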