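#!/usr/bin/env Rscript
# Background effects and mutational bias: per trait, test the
# background-specific bias interaction first, drop it when non-significant,
# then test the background difference and the mutational bias by 1-df
# likelihood-ratio tests, with Levene's check of variance homogeneity on the
# final-model residuals.

suppressPackageStartupMessages(library(mutcov))

pheno <- read_table_csv("results/phenotypes.csv")
pheno$genotype <- factor(pheno$genotype, levels = c("N2", "PB306"))
pheno$ma_status <- factor(pheno$ma_status, levels = c("ancestor", "MA"))

bias <- mutational_bias_analysis(pheno)
write_table_csv(bias, "results/bias_table.csv")
print(bias, digits = 3)

cat("\ninteraction dropped for",
    sum(bias$interaction_dropped), "of 6 traits;",
    sum(bias$background_p < 0.05), "significant background effects,",
    sum(bias$bias_p < 0.05), "significant mutational biases\n")
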