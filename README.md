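# mutcov

Estimation and comparison of **mutational (co)variance matrices** (**M**) for
locomotion behavior traits in *Caenorhabditis elegans*, and their comparison
with standing genetic (co)variance (**G**) matrices.

New mutations do not affect traits independently: pleiotropy gives every
mutation correlated effects across traits, and the matrix **M** — mutational
variances on the diagonal, mutational covariances off it — summarizes that
input per generation. Whether **M** differs between genotypes, and whether it
aligns with the standing **G** matrix of a population, determines how
predictable short-term phenotypic evolution can be. This package implements a
complete, simulation-testable pipeline for that question, using six
locomotion traits: the transition rates between **still (S)**, **forward
(F)** and **backward (B)** movement states (SF, SB, FS, FB, BS, BF), analyzed
on the natural-log scale.

It is written for quantitative geneticists working with mutation-accumulation
(MA) line panels and worm-tracker output, but every stage runs on synthetic
data with known ground truth.

## What it computes

1. **Transition rates** (`ctmc.R`). Movement states observed at 4 Hz are a
   discretely observed continuous-time Markov chain with generator **Q**,
   where off-diagonal rates `q_ij ≥ 0` and `q_ii = −Σ_{j≠i} q_ij`. The
   likelihood of the one-frame transition counts `n_ij` is
   `Σ_ij n_ij log [exp(QΔt)]_ij`; the six free rates are estimated by
   maximum likelihood in log space (`fit_rates()`), with an optional
   Metropolis sampler for posterior-mean parity.
2. **Background effects and mutational bias** (`varcomp.R`). Per trait, the
   linear mixed model
   `ln(q) = α + β_MA + δ_PB306 + η_MA(PB306) + line + block + ε`
   is fitted with lme4; effects are tested by 1-df likelihood-ratio tests
   (interaction first), and variance homogeneity across the four
   genotype × MA groups by Levene's test on the final-model residuals.
3. **M matrices** (`mcmc.R`, `src/gibbs.cpp`). The six traits are fitted as
   a multivariate response with temperature, humidity and log-density
   covariates and line/block random effects, by a Gibbs sampler with
   inverse-Wishart full conditionals (prior: df = 7, scale =
   diag(phenotypic variances)). **M** = ½ × line covariance (inbred lines
   are homozygous). Permutation nulls come from refitting after shuffling
   line and block labels.
4. **Matrix comparison** (`compare.R`). Eigendecomposition and `mmax`;
   folded angles Θ ∈ [0°, 90°] between leading eigenvectors with their
   random-vector null (mean 45° in dimension 2, larger in higher
   dimensions); projection statistics Π = v'Mv / (‖v‖² λ_max) and the null
   Π₀ = λ̄/λ_max; the 83% credible-interval overlap rule.
5. **Eigentensor analysis** (`tensor.R`). Across a set of standardized
   matrices, the covariance of matrix elements S is eigen-decomposed into
   eigentensors E₁, E₂, …; coordinates of each matrix in each eigentensor,
   per-eigentensor eigenvectors (e11), permutation-null bands and posterior
   projection.
6. **Synthetic data** (`synthetic.R`). Exact (Gillespie) CTMC simulation
   sampled at frame times, and phenotype tables generated from the same
   mixed model the pipeline fits, with line covariance 2**M**. Defaults
   mirror the study design: 54 and 62 MA lines for the N2 and PB306
   founders, 16 blocks, two plates per line.

## Worked example

```r
library(mutcov)
set.seed(42)

# simulate 100 MA lines, 2 plates each, from a known M
des <- simulation_design(n_lines = 100, plates_per_line = 2)
ph  <- simulate_phenotypes(des)

fit <- fit_mmatrix_model(ph, n_iter = 20000, burnin = 2000, thin = 10, seed = 7)
M   <- m_matrix(fit)
sum(diag(des$true_M))   # 0.3    — generating total mutational variance
sum(diag(M$mean))       # 0.268  — posterior-mean trace(M)

es <- eigen_summary(M$mean)
es$values[1]            # 0.093  — leading mutational eigenvalue (lambda of mmax)

set.seed(1)
null_angle_samples(2, 1e5)$mean   # 44.9 — the 2-d folded-angle null
null_angle_samples(6, 1e5)$mean   # 69.5 — higher in dimension 6
```

The posterior-mean trace (0.268 vs a generating 0.3) shows the ~10%
shrinkage expected from the inverse-Wishart prior at 100 lines; the 95%
credible intervals cover all six generating mutational variances in this
run. The null angle means are what the folded angle between two independent
random directions looks like — the reference against which an observed
`mmax` vs `gmax` angle is judged.

The `analysis/` directory holds the narrative workflow (simulate →
transition rates → bias table → M matrices with permutation nulls →
comparison → eigentensor analysis); run the numbered scripts in order from
the repository root, outputs land in `results/`.

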