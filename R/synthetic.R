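#' Design for simulating discretely observed movement-state chains
#'
#' @param Q generating rate matrix (per-second rates).
#' @param duration length of each track in seconds.
#' @param frame_rate observation rate in frames per second (tracking movies
#'   are standardized to 4 Hz).
#' @param n_objects number of tracked objects (worms) to simulate.
#' @return a `ctmc_design` list.
#' @export
ctmc_design <- function(Q = default_Q(), duration = 60, frame_rate = 4,
                        n_objects = 1) {
  validate_rate_matrix(Q)
  if (duration <= 0) stop("`duration` must be positive")
  if (frame_rate <= 0) stop("`frame_rate` must be positive")
  if (n_objects < 1) stop("`n_objects` must be >= 1")
  structure(list(Q = Q, duration = duration, frame_rate = frame_rate,
                 n_objects = n_objects), class = "ctmc_design")
}

#' Plausible wild-type rate matrix used as simulation default
#'
#' Rates (per second) chosen so that worms are mostly moving forward with
#' occasional stops and brief reversals, matching the magnitudes seen in
#' tracked populations.
#' @return a `rate_matrix`.
#' @export
default_Q <- function() {
  rate_matrix(c(SF = 0.45, SB = 0.12, FS = 1.10, FB = 0.10,
                BS = 1.40, BF = 0.80))
}

#' Simulate movement-state sequences by exact continuous-time simulation
#'
#' For each object the embedded jump chain is simulated with exponential
#' holding times (Gillespie), then the continuous path is read off at the
#' frame times 0, 1/frame_rate, 2/frame_rate, ...
#'
#' @param design a [ctmc_design()].
#' @param start optional start state or probability vector over (S, F, B);
#'   defaults to the stationary distribution of `Q`.
#' @return data frame with columns `object_id`, `frame_index`, `state`.
#' @export
simulate_state_sequences <- function(design, start = NULL) {
  stopifnot(inherits(design, "ctmc_design"))
  Q <- unclass(design$Q)
  exit <- -diag(Q)
  jump_prob <- Q
  diag(jump_prob) <- 0
  for (i in seq_len(3)) if (exit[i] > 0) jump_prob[i, ] <- jump_prob[i, ] / exit[i]

  if (is.null(start)) {
    start_p <- if (all(exit == 0)) c(1, 0, 0) else stationary_distribution(design$Q)
  } else if (is.character(start)) {
    start_p <- as.numeric(STATES == start)
    if (sum(start_p) != 1) stop("unknown start state")
  } else start_p <- start / sum(start)

  n_frames <- floor(design$duration * design$frame_rate) + 1L
  frame_times <- (seq_len(n_frames) - 1L) / design$frame_rate

  out <- vector("list", design$n_objects)
  for (obj in seq_len(design$n_objects)) {
    s <- sample.int(3, 1, prob = start_p)
    # collect jump times and the state holding after each jump
    # (preallocated with doubling: long tracks have many jumps)
    cap <- 256L
    jump_t <- numeric(cap); jump_s <- integer(cap)
    jump_t[1] <- 0; jump_s[1] <- s
    k <- 1L
    t <- 0
    while (t < design$duration) {
      if (exit[s] <= 0) break   # absorbing state
      t <- t + stats::rexp(1, exit[s])
      if (t >= design$duration) break
      s <- sample.int(3, 1, prob = jump_prob[s, ])
      k <- k + 1L
      if (k > cap) {
        cap <- cap * 2L
        length(jump_t) <- cap
        length(jump_s) <- cap
      }
      jump_t[k] <- t
      jump_s[k] <- s
    }
    state_idx <- jump_s[findInterval(frame_times, jump_t[seq_len(k)])]
    out[[obj]] <- data.frame(object_id = obj,
                             frame_index = seq_len(n_frames) - 1L,
                             state = STATES[state_idx])
  }
  do.call(rbind, out)
}

#' Split a state-sequence table into per-object label vectors
#' @param df data frame with `object_id`, `frame_index`, `state`.
#' @return list of character vectors ordered by frame index.
#' @export
state_sequence_list <- function(df) {
  df <- df[order(df$object_id, df$frame_index), ]
  split(df$state, df$object_id)
}

#' Default mutational covariance matrix for the six log transition rates
#'
#' A positive-definite 6x6 matrix in squared-log-rate units with diagonal
#' mutational variances of 0.05 and mild positive correlations (0.3) between
#' rates sharing a movement state, emulating pleiotropic mutational input.
#' @return 6x6 matrix with trait dimnames.
#' @export
default_M <- function() {
  v <- rep(0.05, 6)
  R <- diag(6)
  shared <- outer(TRAITS, TRAITS, function(a, b)
    substr(a, 1, 1) == substr(b, 1, 1) | substr(a, 2, 2) == substr(b, 2, 2))
  R[shared & row(R) != col(R)] <- 0.3
  M <- diag(sqrt(v)) %*% R %*% diag(sqrt(v))
  dimnames(M) <- list(TRAITS, TRAITS)
  M
}

#' Simulation design for plate-level phenotypes under the mixed model
#'
#' Generates data under the model the pipeline fits: each plate row is
#' group mean + covariate effects + line effect + block effect + residual,
#' with line effects multivariate normal with covariance `2 * true_M`
#' (homozygous inbred lines: M is half the among-line covariance).
#'
#' @param n_lines number of lines in the group.
#' @param n_blocks number of assay blocks.
#' @param plates_per_line plates (replicate assays) per line, each assigned
#'   to a different random block (lines are typically assayed in two blocks).
#' @param true_M 6x6 PSD mutational covariance; line covariance is `2*true_M`.
#' @param true_block_cov 6x6 PSD block covariance.
#' @param true_residual_cov 6x6 positive-definite residual covariance.
#' @param covariate_effects 6x3 matrix of per-trait effects of (temperature,
#'   humidity, log density), applied to centered covariates.
#' @param group_mean 6-vector of trait means on the natural-log scale.
#' @param covariate_dist list of `mean`/`sd` 3-vectors for the covariates.
#' @param line_variance_multiplier multiplier on `true_M` for the line
#'   covariance; 2 for homozygous inbred lines, 0 for an ancestor group
#'   carrying no accumulated mutations.
#' @return a `simulation_design` list.
#' @export
simulation_design <- function(n_lines = 54, n_blocks = 16, plates_per_line = 2,
                              true_M = default_M(),
                              true_block_cov = diag(0.02, 6),
                              true_residual_cov = diag(0.12, 6),
                              covariate_effects = default_covariate_effects(),
                              group_mean = default_group_mean(),
                              covariate_dist = list(mean = c(20, 50, 6.9),
                                                    sd = c(0.5, 5, 0.2)),
                              line_variance_multiplier = 2) {
  for (nm in c("true_M", "true_block_cov", "true_residual_cov")) {
    S <- get(nm)
    if (!isSymmetric(unname(S), tol = 1e-8))
      stop(nm, " must be symmetric")
    if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
      stop(nm, " must be positive semi-definite")
  }
  if (min(eigen(true_residual_cov, symmetric = TRUE,
                only.values = TRUE)$values) <= 0)
    stop("true_residual_cov must be positive definite")
  if (n_lines < 1 || n_blocks < 1 || plates_per_line < 1)
    stop("counts must be >= 1")
  structure(list(n_lines = n_lines, n_blocks = n_blocks,
                 plates_per_line = plates_per_line, true_M = true_M,
                 true_block_cov = true_block_cov,
                 true_residual_cov = true_residual_cov,
                 covariate_effects = covariate_effects,
                 group_mean = group_mean, covariate_dist = covariate_dist,
                 line_variance_multiplier = line_variance_multiplier),
            class = "simulation_design")
}

#' @rdname simulation_design
#' @export
default_covariate_effects <- function() {
  # modest environmental sensitivity of log rates per unit covariate
  eff <- cbind(temperature = rep(0.05, 6),
               humidity = rep(-0.005, 6),
               logdens = rep(-0.10, 6))
  rownames(eff) <- TRAITS
  eff
}

#' @rdname simulation_design
#' @export
default_group_mean <- function() {
  # log rates of the default Q: a plausible wild-type baseline
  setNames(log(rates_from_matrix(default_Q())), TRAITS)
}

# PSD-safe multivariate normal draws
rmvn <- function(n, Sigma) {
  d <- nrow(Sigma)
  if (all(Sigma == 0)) return(matrix(0, n, d))
  matrix(MASS::mvrnorm(n, mu = rep(0, d), Sigma = Sigma, tol = 1e-8),
         nrow = n, ncol = d)
}

#' Simulate a plate-level phenotype table for one group of lines
#'
#' @param design a [simulation_design()].
#' @param line_prefix,genotype,ma_status labels stamped on every row.
#' @param block_ids optional block identifiers to draw from (default
#'   `1:n_blocks`); lets several groups share one block structure.
#' @param block_effects optional matrix of block effects (rows named by
#'   block id) shared with other groups assayed in the same blocks; drawn
#'   from `true_block_cov` when absent.
#' @return data frame with columns `line_id`, `block_id`, `genotype`,
#'   `ma_status`, `temperature`, `humidity`, `logdens` and the six trait
#'   columns `ln_SF` ... `ln_BF`. The latent line effects are attached as
#'   attribute `line_effects` for calibration checks.
#' @export
simulate_phenotypes <- function(design, line_prefix = "L", genotype = "N2",
                                ma_status = "MA", block_ids = NULL,
                                block_effects = NULL) {
  stopifnot(inherits(design, "simulation_design"))
  d <- 6
  if (is.null(block_ids)) block_ids <- paste0("B", seq_len(design$n_blocks))
  n_blocks <- length(block_ids)

  line_eff <- rmvn(design$n_lines,
                   design$line_variance_multiplier * design$true_M)
  if (is.null(block_effects)) {
    block_eff <- rmvn(n_blocks, design$true_block_cov)
    rownames(block_eff) <- block_ids
  } else {
    if (!all(block_ids %in% rownames(block_effects)))
      stop("`block_effects` must cover all block ids")
    block_eff <- block_effects[block_ids, , drop = FALSE]
  }

  rows <- vector("list", design$n_lines)
  ppl <- min(design$plates_per_line, n_blocks)
  for (l in seq_len(design$n_lines)) {
    blocks <- sample(block_ids, ppl)
    rows[[l]] <- data.frame(line_id = paste0(line_prefix, l),
                            block_id = blocks, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  n <- nrow(tab)

  cv <- design$covariate_dist
  covars <- cbind(temperature = rnorm(n, cv$mean[1], cv$sd[1]),
                  humidity = rnorm(n, cv$mean[2], cv$sd[2]),
                  logdens = rnorm(n, cv$mean[3], cv$sd[3]))
  covars_c <- sweep(covars, 2, cv$mean)

  line_idx <- as.integer(factor(tab$line_id,
                                levels = paste0(line_prefix,
                                                seq_len(design$n_lines))))
  y <- matrix(rep(design$group_mean, each = n), n, d) +
    covars_c %*% t(design$covariate_effects) +
    line_eff[line_idx, , drop = FALSE] +
    block_eff[tab$block_id, , drop = FALSE] +
    rmvn(n, design$true_residual_cov)
  colnames(y) <- paste0("ln_", TRAITS)

  out <- cbind(data.frame(line_id = tab$line_id, block_id = tab$block_id,
                          genotype = genotype, ma_status = ma_status,
                          stringsAsFactors = FALSE),
               as.data.frame(covars), as.data.frame(y))
  rownames(line_eff) <- paste0(line_prefix, seq_len(design$n_lines))
  attr(out, "line_effects") <- line_eff
  out
}

#' Designs for the four-group mutation-accumulation experiment
#'
#' Two founder genotypes (N2, PB306) each with an ancestor and a set of
#' 250-generation MA lines. Defaults mirror the study conditions: 54 N2 and
#' 62 PB306 MA lines in 16 shared blocks, most lines assayed twice, ancestors
#' replicated across blocks. Group means carry the background differences
#' (`delta`) and mutational biases (`beta_ma`), applied on the natural-log
#' scale; an optional interaction `eta` shifts only the PB306 MA group.
#' Ancestors carry no accumulated mutations, so their line-level covariance
#' multiplier is zero.
#'
#' @param base passed through [simulation_design()] as the template for all
#'   four groups.
#' @param delta 6-vector: PB306 minus N2 background difference per trait.
#' @param beta_ma 6-vector: MA minus ancestor shift (mutational bias).
#' @param eta 6-vector: extra shift of the PB306 MA group (interaction).
#' @param n_ma_lines integer 2-vector: MA lines for N2 and PB306.
#' @param residual_scale named numeric multipliers on the residual covariance
#'   per group (for heteroskedasticity experiments), names among
#'   `N2_ancestor`, `N2_MA`, `PB306_ancestor`, `PB306_MA`.
#' @return named list of four `simulation_design` objects plus labels.
#' @export
ma_experiment_designs <- function(base = simulation_design(),
                                  delta = c(0.44, 0.37, -0.50, 0.16, 0.05, 0.51),
                                  beta_ma = c(0.010, 0.004, 0.188, 0.199, 0.094, 0.221),
                                  eta = rep(0, 6),
                                  n_ma_lines = c(N2 = 54, PB306 = 62),
                                  residual_scale = NULL) {
  groups <- list()
  mk <- function(n_lines, mean_shift, mult, scale) {
    d <- base
    d$n_lines <- n_lines
    d$group_mean <- base$group_mean + mean_shift
    d$line_variance_multiplier <- mult
    d$true_residual_cov <- base$true_residual_cov * scale
    class(d) <- "simulation_design"
    d
  }
  sc <- function(nm) {
    if (is.null(residual_scale) || is.null(residual_scale[[nm]])) 1
    else residual_scale[[nm]]
  }
  groups$N2_ancestor <- mk(1, rep(0, 6), 0, sc("N2_ancestor"))
  groups$N2_MA <- mk(n_ma_lines[["N2"]], beta_ma, 2, sc("N2_MA"))
  groups$PB306_ancestor <- mk(1, delta, 0, sc("PB306_ancestor"))
  groups$PB306_MA <- mk(n_ma_lines[["PB306"]], delta + beta_ma + eta, 2,
                        sc("PB306_MA"))
  groups
}

#' Simulate the combined four-group MA experiment table
#'
#' Ancestor "lines" are the founder genotypes themselves, replicated across
#' all blocks (as in the assay design); MA lines get `plates_per_line` plates
#' each. All groups share one set of block identities (and block effects are
#' redrawn per group's design covariance within each group).
#'
#' @param designs output of [ma_experiment_designs()], or a compatible named
#'   list with the four `genotype_mastatus` groups.
#' @return single phenotype table suitable for the background-effects model,
#'   with `genotype` in `{N2, PB306}` and `ma_status` in `{ancestor, MA}`.
#' @export
simulate_ma_experiment <- function(designs = ma_experiment_designs()) {
  need <- c("N2_ancestor", "N2_MA", "PB306_ancestor", "PB306_MA")
  if (!all(need %in% names(designs)))
    stop("missing group design(s): ",
         paste(setdiff(need, names(designs)), collapse = ", "))
  n_blocks <- designs$N2_MA$n_blocks
  block_ids <- paste0("B", seq_len(n_blocks))
  # blocks are shared assay days: one set of block effects for all groups
  block_eff <- rmvn(n_blocks, designs$N2_MA$true_block_cov)
  rownames(block_eff) <- block_ids
  pieces <- lapply(need, function(nm) {
    d <- designs[[nm]]
    genotype <- sub("_(ancestor|MA)$", "", nm)
    ma_status <- sub("^.*_", "", nm)
    if (ma_status == "ancestor") {
      # founder replicated in (nearly) every block
      d$plates_per_line <- n_blocks
    }
    simulate_phenotypes(d, line_prefix = paste0(nm, "_"),
                        genotype = genotype, ma_status = ma_status,
                        block_ids = block_ids, block_effects = block_eff)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out$genotype <- factor(out$genotype, levels = c("N2", "PB306"))
  out$ma_status <- factor(out$ma_status, levels = c("ancestor", "MA"))
  out
}

#' Write / read tables in the package's plain-CSV interchange format
#' @param x data frame.
#' @param path file path.
#' @export
write_table_csv <- function(x, path) {
  write.csv(x, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
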