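#!/usr/bin/env Rscript
# Eigentensor analysis across three standardized (co)variance matrices: the
# two M matrices and a synthetic standing-variation G matrix with inflated
# covariances among rates leaving the still state (the pattern a
# lab-adapted population shows relative to mutational input). Trait columns
# are standardized to a common phenotypic scale before fitting, the
# element-covariance matrix S is eigen-decomposed, and posterior draws are
# projected onto the fixed eigentensors.

suppressPackageStartupMessages(library(mutcov))

pheno <- read_table_csv("results/phenotypes.csv")
set.seed(106106)
traits <- paste0("ln_", c("SF", "SB", "FS", "FB", "BS", "BF"))

# synthetic lab-population sample: one "genotype" with many lines whose
# line-level covariance (the G matrix) has extra (co)variance in SF/SB
G_true <- 2 * default_M()
G_true[1:2, ] <- G_true[1:2, ] * 1.6
G_true[, 1:2] <- G_true[, 1:2] * 1.6
g_design <- simulation_design(n_lines = 150, n_blocks = 16,
                              plates_per_line = 2,
                              true_M = G_true / 2)  # line cov = G_true
g_tab <- simulate_phenotypes(g_design, line_prefix = "A6140_",
                             genotype = "A6140", ma_status = "standing")

groups <- list(
  N2 = pheno[pheno$genotype == "N2" & pheno$ma_status == "MA", ],
  PB306 = pheno[pheno$genotype == "PB306" & pheno$ma_status == "MA", ],
  A6140 = g_tab)

posts <- lapply(groups, function(tab) {
  std <- standardize_traits(tab, traits)
  fit <- fit_mmatrix_model(std, n_iter = 20000, burnin = 2000, thin = 10)
  m_matrix(fit)   # for the standing population this is G/2-scaled the same way
})
# put all three on the same footing: the line covariance itself
mats <- lapply(posts, function(p) 2 * p$mean)
post_draws <- lapply(posts, function(p) p$samples * 2)

td <- eigentensor_decomposition(build_s_matrix(mats))
coords <- tensor_coordinates(mats, td, k = 2)
tp <- tensor_posterior(post_draws, td, k = 2)

cat("alpha:", round(td$alpha[1:2], 4),
    " (", round(100 * td$alpha_prop[1:2]), "% )\n")
cat("coordinates in E1:\n"); print(round(coords[, 1], 3))
e11 <- td$tensor_eigen[[1]]$vectors[, 1]
names(e11) <- traits
lam <- td$tensor_eigen[[1]]$values
cat("e11 (", round(100 * lam[1]^2 / sum(lam^2)), "% of E1 variation):\n")
print(round(e11, 3))

g_eig <- eigen_summary(mats$A6140)
for (g in c("N2", "PB306")) {
  m_eig <- eigen_summary(mats[[g]])
  ang <- vector_angle(g_eig$mmax, m_eig$mmax)
  pp <- pi_posterior(post_draws[[g]], g_eig$mmax)
  cat(sprintf("%s: angle(mmax, gmax) = %.1f deg; Pi along gmax %.3f [%s] vs Pi0 %.3f\n",
              g, ang, mean(pp$pi),
              paste(round(pp$intervals$pi["83%", ], 3), collapse = ", "),
              mean(pp$pi0)))
}

jsonlite::write_json(
  list(alpha = td$alpha[1:2], alpha_prop = td$alpha_prop[1:2],
       coordinates = coords, e11 = e11,
       alpha_posterior_83 = tp$intervals$alpha[[1]]["83%", ]),
  "results/tensor.json", auto_unbox = TRUE, pretty = TRUE, digits = NA,
  force = TRUE)
cat("wrote results/tensor.json\n")
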