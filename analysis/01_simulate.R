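#!/usr/bin/env Rscript
# Simulate the study's inputs: the four-group mutation-accumulation
# phenotype table (two founder genotypes, their MA lines, 16 shared assay
# blocks) and a batch of 4 Hz movement-state sequences from a known rate
# matrix. Everything downstream re-estimates what was generated here.

suppressPackageStartupMessages(library(mutcov))
dir.create("results", showWarnings = FALSE)

set.seed(101101)

designs <- ma_experiment_designs()
pheno <- simulate_ma_experiment(designs)
write_table_csv(pheno, "results/phenotypes.csv")
cat("phenotypes:", nrow(pheno), "plate rows,",
    length(unique(pheno$line_id)), "lines\n")

# one simulated plate's worth of tracked objects at 4 Hz
cd <- ctmc_design(Q = default_Q(), duration = 60, frame_rate = 4,
                  n_objects = 50)
states <- simulate_state_sequences(cd)
write_table_csv(states, "results/state_sequences.csv")
cat("state sequences:", length(unique(states$object_id)), "objects x",
    max(states$frame_index) + 1, "frames\n")

# stash the generating truth for later comparison (plain CSV, not consumed
# by any estimation step)
write_table_csv(as.data.frame(designs$N2_MA$true_M), "results/true_M.csv")
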