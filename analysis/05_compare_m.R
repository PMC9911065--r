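#!/usr/bin/env Rscript
# Compare the two genotypes' M matrices: total genetic variance (trace) with
# permutation-null bands and the 83% interval-overlap rule, eigenvalues
# against rotated nulls, the folded angle between the two mmax directions
# with its random-vector null, and the projection statistics Pi / Pi0.
#
# The multivariate fits are re-run here (they are cheap at these settings)
# so this stage depends only on the phenotype table.

suppressPackageStartupMessages(library(mutcov))

pheno <- read_table_csv("results/phenotypes.csv")
set.seed(105105)

fits <- lapply(c(N2 = "N2", PB306 = "PB306"), function(g) {
  sub <- pheno[pheno$genotype == g & pheno$ma_status == "MA", ]
  m_matrix(fit_mmatrix_model(sub, n_iter = 20000, burnin = 2000, thin = 10))
})

nulls <- lapply(c(N2 = "N2", PB306 = "PB306"), function(g) {
  flat <- as.matrix(read_table_csv(
    file.path("results", paste0("null_M_", g, ".csv"))))
  arr <- array(t(flat), c(6, 6, nrow(flat)))
  trace <- read_table_csv(file.path("results",
                                    paste0("null_trace_", g, ".csv")))$trace
  structure(list(samples = arr, trace = trace), class = "null_m_set")
})

cmp <- compare_m_matrices(fits$N2, fits$PB306, nulls$N2, nulls$PB306)

null_angle <- null_angle_samples(6, 1000)

cat("trace(M):  N2", round(cmp$trace$a, 4),
    " PB306", round(cmp$trace$b, 4),
    " different at 83% CI rule:", cmp$trace$different, "\n")
cat("N2 trace exceeds null band:", cmp$trace$a_exceeds_null,
    "; PB306:", cmp$trace$b_exceeds_null, "\n")
cat("angle(mmax_N2, mmax_PB306):", round(cmp$angle_mmax, 1),
    "degrees; null mean", round(null_angle$mean, 1),
    "[", paste(round(null_angle$intervals["95%", ], 1), collapse = ", "),
    "]\n")
cat("lambda_1:  N2", round(cmp$lambda$a[1], 4),
    " PB306", round(cmp$lambda$b[1], 4), "\n")
cat("Pi (N2 along PB306 mmax):",
    round(mean(cmp$pi$a_on_b$pi), 3),
    " vs Pi0", round(mean(cmp$pi$a_on_b$pi0), 3), "\n")
cat("Pi (PB306 along N2 mmax):",
    round(mean(cmp$pi$b_on_a$pi), 3),
    " vs Pi0", round(mean(cmp$pi$b_on_a$pi0), 3), "\n")

jsonlite::write_json(
  list(trace = cmp$trace, angle_mmax = cmp$angle_mmax,
       null_angle_mean = null_angle$mean,
       lambda = cmp$lambda,
       pi_intervals = list(a_on_b = cmp$pi$a_on_b$intervals,
                           b_on_a = cmp$pi$b_on_a$intervals)),
  "results/compare.json", auto_unbox = TRUE, pretty = TRUE, digits = NA,
  force = TRUE)
cat("wrote results/compare.json\n")
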