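#' Univariate mixed model for background effects and mutational bias
#'
#' Fits, for one log transition rate, the model
#'
#'   `ln(q) = alpha_N2 + beta_MA + delta_PB306 + eta_MA(PB306) + line + block + e`
#'
#' with treatment contrasts anchored at the N2 ancestor: `alpha` is the N2
#' founder mean, `beta_MA` the ancestor-to-MA shift in the N2 background
#' (mutational bias), `delta_PB306` the founder background difference and
#' `eta` the background-specific bias (interaction). Line and block enter as
#' independent random intercepts.
#'
#' @param table phenotype table with `genotype`, `ma_status`, `line_id`,
#'   `block_id` and the trait column.
#' @param trait trait column name (e.g. `"ln_SF"`).
#' @param include_interaction keep the `eta` interaction term?
#' @param include_ma,include_background drop `beta_MA` / `delta_PB306` to
#'   build the reduced models of a likelihood-ratio test.
#' @param method `"ML"` (required for fixed-effect LRTs) or `"REML"`.
#' @return an `lmm_fit` list: `coefficients` (estimate, se per fixed effect),
#'   `varcomp` (line, block, residual variances), `loglik`, `method`,
#'   `n_fixed`, `trait` and the underlying `lme4` fit as `model`.
#' @export
fit_univariate_lmm <- function(table, trait, include_interaction = TRUE,
                               include_ma = TRUE, include_background = TRUE,
                               method = c("ML", "REML")) {
  method <- match.arg(method)
  if (!trait %in% names(table)) stop("missing trait column: ", trait)
  tab <- droplevels(table)
  tab$ma_status <- factor(tab$ma_status, levels = c("ancestor", "MA"))
  tab$genotype <- factor(tab$genotype)
  if (length(unique(tab$line_id)) < 2 || length(unique(tab$block_id)) < 2)
    stop("need at least 2 lines and 2 blocks")

  if (include_interaction) {
    cells <- table(tab$genotype, tab$ma_status)
    if (any(cells == 0)) {
      miss <- which(cells == 0, arr.ind = TRUE)[1, ]
      stop("design cell absent: genotype ", rownames(cells)[miss[1]],
           " x ma_status ", colnames(cells)[miss[2]])
    }
  }

  terms <- c(if (include_ma) "ma_status",
             if (include_background) "genotype",
             if (include_interaction) "ma_status:genotype")
  rhs <- paste(c(if (length(terms)) terms else "1",
                 "(1 | line_id)", "(1 | block_id)"), collapse = " + ")
  form <- as.formula(paste(trait, "~", rhs))
  fit <- lme4::lmer(form, data = tab, REML = (method == "REML"),
                    control = lme4::lmerControl(check.conv.singular = "ignore"))

  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  varcomp <- setNames(vc$vcov, vc$grp)
  names(varcomp)[names(varcomp) == "line_id"] <- "line"
  names(varcomp)[names(varcomp) == "block_id"] <- "block"
  names(varcomp)[names(varcomp) == "Residual"] <- "residual"

  structure(list(coefficients = data.frame(term = names(fe),
                                           estimate = unname(fe),
                                           se = unname(se)),
                 varcomp = varcomp,
                 loglik = as.numeric(logLik(fit)),
                 method = method, n_fixed = length(fe), trait = trait,
                 model = fit),
            class = "lmm_fit")
}

#' Likelihood-ratio test between nested mixed-model fits
#'
#' The statistic `2 (l_full - l_reduced)` is referred to a chi-squared
#' distribution with degrees of freedom equal to the difference in
#' fixed-effect count (one for the single-term tests used here). Fixed-effect
#' LRTs require ML fits; REML likelihoods are not comparable across
#' fixed-effect structures and are rejected.
#'
#' @param full,reduced `lmm_fit` objects with `reduced` nested in `full`.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
lrt <- function(full, reduced) {
  stopifnot(inherits(full, "lmm_fit"), inherits(reduced, "lmm_fit"))
  if (full$method != "ML" || reduced$method != "ML")
    stop("fixed-effect LRT requires ML fits")
  df <- full$n_fixed - reduced$n_fixed
  if (df < 0) stop("`reduced` has more fixed effects than `full`")
  stat <- max(0, 2 * (full$loglik - reduced$loglik))
  p <- if (df == 0) 1 else pchisq(stat, df = df, lower.tail = FALSE)
  list(statistic = stat, df = df, p_value = p)
}

#' Levene's test for homogeneity of variances
#'
#' Classic form: absolute deviations from the group means, compared across
#' groups with a one-way ANOVA F test.
#'
#' @param values numeric vector (e.g. model residuals).
#' @param groups group labels (>= 2 groups, each with >= 2 observations).
#' @return list with `statistic`, `df`, `p_value`.
#' @export
levene_test <- function(values, groups) {
  groups <- factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs at least 2 observations")
  dev <- abs(values - ave(values, groups))
  a <- anova(lm(dev ~ groups))
  list(statistic = a$`F value`[1], df = c(a$Df[1], a$Df[2]),
       p_value = a$`Pr(>F)`[1])
}

#' @importFrom stats ave
NULL

#' Background-effect and mutational-bias report for all six transition rates
#'
#' Per trait: the background-specific bias interaction is tested first by
#' LRT; when it is not significant at `alpha` it is dropped, and the
#' mutational bias and background effects are then each tested by a 1-df LRT
#' against the interaction-free model. Homogeneity of variances across the
#' four genotype-by-MA groups is checked with Levene's test on the residuals
#' of the final model.
#'
#' @param table four-group phenotype table (see [simulate_ma_experiment()]).
#' @param traits trait columns to analyze.
#' @param alpha level for dropping the interaction.
#' @return data frame with one row per trait: `trait`, `background_effect`,
#'   `background_se`, `background_p`, `bias_effect`, `bias_se`, `bias_p`,
#'   `interaction_p`, `interaction_dropped`, `levene_p`.
#' @export
mutational_bias_analysis <- function(table, traits = paste0("ln_", TRAITS),
                                     alpha = 0.05) {
  cells <- table(table$genotype, table$ma_status)
  if (any(cells == 0)) stop("all four genotype x ma_status groups are required")
  grp <- interaction(table$genotype, table$ma_status, drop = TRUE)

  rows <- lapply(traits, function(tr) {
    full <- fit_univariate_lmm(table, tr, include_interaction = TRUE)
    noint <- fit_univariate_lmm(table, tr, include_interaction = FALSE)
    int_test <- lrt(full, noint)
    dropped <- int_test$p_value >= alpha
    final <- if (dropped) noint else full

    base <- if (dropped) noint else full
    no_ma <- fit_univariate_lmm(table, tr, include_interaction = !dropped,
                                include_ma = FALSE)
    no_bg <- fit_univariate_lmm(table, tr, include_interaction = !dropped,
                                include_background = FALSE)
    ma_test <- lrt(base, no_ma)
    bg_test <- lrt(base, no_bg)

    cf <- final$coefficients
    est <- function(pat) {
      i <- grep(pat, cf$term)
      if (length(i) == 0) c(NA_real_, NA_real_)
      else c(cf$estimate[i[1]], cf$se[i[1]])
    }
    bias <- est("^ma_statusMA$")
    bg <- est("^genotype")
    lev <- levene_test(resid(final$model), grp)
    data.frame(trait = tr,
               background_effect = bg[1], background_se = bg[2],
               background_p = bg_test$p_value,
               bias_effect = bias[1], bias_se = bias[2],
               bias_p = ma_test$p_value,
               interaction_p = int_test$p_value,
               interaction_dropped = dropped,
               levene_p = lev$p_value)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Phenotypic standardization of trait columns
#'
#' Centers each trait to mean zero, then divides every trait by the single
#' scalar `sigma_bar`, the mean of the six per-trait standard deviations.
#' Afterwards each trait has mean 0, the mean of the per-trait standard
#' deviations is 1, and each trait's standard deviation remains proportional
#' to its original value — the common scale on which M and G matrices are
#' compared.
#'
#' @param table phenotype table.
#' @param traits trait columns.
#' @return table with standardized trait columns; the centers and
#'   `sigma_bar` used are attached as attributes.
#' @export
standardize_traits <- function(table, traits = paste0("ln_", TRAITS)) {
  if (nrow(table) < 2) stop("need at least 2 rows")
  Y <- as.matrix(table[, traits])
  mu <- colMeans(Y)
  sds <- apply(Y, 2, sd)
  sbar <- mean(sds)
  if (sbar == 0) stop("all traits are constant: mean standard deviation is zero")
  Z <- sweep(Y, 2, mu) / sbar
  out <- table
  out[, traits] <- Z
  attr(out, "centers") <- mu
  attr(out, "sigma_bar") <- sbar
  out
}
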