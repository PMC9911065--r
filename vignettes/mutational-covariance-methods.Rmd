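---
title: "Models and methods behind mutcov"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mutcov}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutcov)
```

mutcov estimates mutational (co)variance matrices (**M**) for six locomotion
behavior traits of *C. elegans* — the log transition rates between still (S),
forward (F) and backward (B) movement states — and compares them with each
other and with standing genetic (co)variance (**G**) matrices. This vignette
is the package's own account of the models, the tunable parameters, the
numerical choices, and what the synthetic-data checks do and do not
establish.

## Movement states as a continuous-time Markov chain

A tracked worm occupies one of three movement states, and switches with
instantaneous rates $q_{ij} \ge 0$ ($i \neq j$, per second) collected in a
generator matrix $Q$ whose diagonal is constrained to
$q_{ii} = -\sum_{j \neq i} q_{ij}$, so rows sum to zero. The tracker reports
states at a fixed frame rate (4 Hz by default, so $\Delta t = 0.25$ s); over
one frame the transition kernel is the matrix exponential
$P(\Delta t) = e^{Q \Delta t}$, and the likelihood of the observed one-frame
transition counts $n_{ij}$ is

$$\ell(Q) = \sum_{ij} n_{ij} \log P_{ij}(\Delta t).$$

`fit_rates()` maximizes $\ell$ over the six log rates with box-constrained
quasi-Newton (L-BFGS-B). Working in log space keeps every rate positive
without explicit constraints. Point estimation by maximum likelihood stands
in for a Bayesian posterior mean here: with the data volumes of a tracking
movie (tens of thousands of transitions) the posterior is sharply
concentrated and the two coincide to well under a percent, which the
optional random-walk Metropolis sampler (`sample_rates_posterior()`, normal
priors on log rates with sd 10 — effectively flat) is provided to verify.

Numerical choices:

* The naive estimator $\hat q_{ij} = n_{ij} / (n_{i\cdot} \Delta t)$ is the
  starting point; it is exact as $\Delta t \to 0$ and the optimizer can only
  improve on it, which is asserted as an invariant.
* Rates are bounded to $[10^{-8}, 10^3]$ s$^{-1}$. A state never observed as
  a source leaves its two rates unidentifiable: they are pinned at the
  $10^{-8}$ floor and flagged (`"unidentifiable"`), never dropped. Rates
  driven to the floor by all-diagonal counts are flagged `"floored"`.
* Only the discretely observed likelihood is used; within-frame
  self-transitions are unobservable and no path-space reconstruction is
  attempted, matching the observation model of the assay.

The information content of a dataset depends on where the chain spends its
time: a rate of 0.05 s$^{-1}$ leaving a rarely occupied state may be
observed only a few hundred times even in $10^5$ frames, with Monte Carlo
standard errors of several percent. Recovery checks in the test suite are
therefore sized in observed transitions, not frames.

## Background effects and mutational bias

For each trait, the univariate linear mixed model

$$\ln(q_k) = \alpha + \beta_{MA} + \delta_{PB306} + \eta_{MA(PB306)}
  + \zeta_{line} + \eta_{block} + \varepsilon$$

is fitted with lme4, with treatment contrasts anchored at the N2 ancestor:
$\alpha$ is the founder N2 mean, $\beta_{MA}$ the ancestor-to-MA shift
(mutational bias), $\delta_{PB306}$ the founder background difference, and
$\eta$ the background-specific bias. Fixed effects are tested by 1-df
likelihood-ratio tests on ML fits (REML fits are rejected for this purpose,
since REML likelihoods are not comparable across fixed-effect structures).
The interaction is tested first and dropped when non-significant at 0.05;
the remaining two effects are then each tested against the interaction-free
model, and variance homogeneity across the four genotype-by-MA groups is
checked with Levene's test on the final model's residuals. Levene's test
uses absolute deviations from group *means* (the classic form); whether to
center at means or medians was an open choice, and mean-centering was chosen
for its exact correspondence with the one-way ANOVA F oracle used in the
tests.

A structural subtlety: each ancestor is a single genotype replicated across
blocks, so its "line" effect is exactly zero by construction — the founder
defines the group baseline. The mixed model nevertheless assigns it the
line-level variance, which makes the $\beta_{MA}$ test mildly conservative
on data generated this way. The calibration checks therefore use a
well-specified null generator (two groups of lines with identical line-level
variance and genuinely shared block effects), where the LRT p-values are
uniform to Kolmogorov–Smirnov precision at 500 replicates.

## The multivariate model and M

The six traits are fitted jointly:

$$\mathbf{y}_i = \boldsymbol\mu + B_T T_i + B_H H_i + B_D D_i
  + \mathbf{u}_{line(i)} + \mathbf{w}_{block(i)} + \mathbf{e}_i$$

with $\mathbf{u} \sim N(0, G_{line})$, $\mathbf{w} \sim N(0, G_{block})$,
$\mathbf{e} \sim N(0, R)$, all $6 \times 6$. Estimation is by a Gibbs
sampler written for this model (RcppArmadillo): multivariate-normal full
conditionals for the fixed effects and each random-effect vector,
inverse-Wishart full conditionals for the three covariance matrices.
Because MA lines are fully homozygous after 250 generations of selfing,
**M** is defined as half the line covariance matrix,
$\mathbf{M} = \tfrac12 G_{line}$.

Choices that matter:

* **Prior.** Each covariance matrix gets an inverse-Wishart prior with
  scale the diagonal matrix of empirical phenotypic variances and degrees
  of freedom $\nu_0 = d + 1 = 7$, the weakest choice that keeps the prior
  proper. Both are configurable (`prior_nu`, `prior_scale`). This prior
  pulls small variance components toward its scale; at 100 lines the
  posterior-mean trace of **M** sits ~8–10% below the generating value,
  which is the expected and observed shrinkage, inside the 20% recovery
  band the tests assert.
* **Centering.** Covariates are mean-centered before fitting so the
  intercepts are trait means and the sampler's fixed-effect conditional is
  well-conditioned.
* **Settings.** Study-scale settings are 500,000 iterations, 50,000
  burn-in, thinning 10. The simulation checks in this package run at
  20,000/2,000/10 (fits) and a few thousand iterations per permutation
  refit — deliberately scaled-down settings that keep a full calibration
  run on one core in minutes. At these settings the stored-chain lag-1
  autocorrelation typically sits above the 0.05 threshold that study-scale
  chains are held to; `fit_mmatrix_model()` reports the diagnostic and
  flags it, and longer thinning restores the threshold when needed.
* **Determinism.** The sampler draws all randomness from R's RNG, so a
  seed makes the entire sample stream reproducible, which the tests assert
  exactly.
* **Efficiency.** Levels (lines, blocks) sharing a replicate count share
  their conditional precision matrix, so they are updated with a single
  Cholesky factorization per count per iteration — the update is a handful
  of dense $6 \times k$ solves rather than hundreds of small ones.

Permutation nulls (`randomized_null_m()`) shuffle line labels and block
labels independently across plate rows and refit, storing the
posterior-mean **M** of each replicate. This preserves row count and trait
marginals while destroying line and block structure; each row keeps its own
covariates. Null bands are equal-tailed quantiles across replicates (1,000
at study scale; 100 in the desk-scale checks).

## Comparison statistics

`eigen_summary()` orders eigenvalues descending and fixes each
eigenvector's sign by making its largest-magnitude coordinate positive —
a reporting convention only, since an axis is defined up to sign. When
$\lambda_1 - \lambda_2 < 10^{-8}$ the leading axis is flagged as
ill-defined. The folded angle between two leading axes,

$$\Theta = \tfrac{180}{\pi}\cos^{-1}
  \frac{|v_1 \cdot v_2|}{\|v_1\|\|v_2\|} \in [0^\circ, 90^\circ],$$

is compared against the distribution of angles between random vectors with
coordinates uniform on $(-1,1)$: exactly $45^\circ$ in expectation in
dimension 2 (by the four-fold symmetry of the square), and larger in higher
dimensions, approaching $90^\circ$ as dimension grows. The projection
statistic $\Pi = v^\top M v / (\|v\|^2 \lambda_{max})$ measures how much of
a matrix's maximal variance lies along another matrix's leading axis, with
null expectation $\Pi_0 = \bar\lambda / \lambda_{max}$.

Credible intervals throughout are equal-tailed sample quantiles, not
highest-posterior-density intervals: the 83% interval-overlap rule for
declaring two posterior distributions different is defined on equal-tailed
intervals, and quantile intervals are directly testable against an
order-statistics oracle. Under variance homogeneity the 83% rule gives an
approximate 5% pairwise comparison; the calibration test confirms the
false-positive rate stays below 17%.

## Eigentensor analysis

To compare a *set* of matrices, each is vectorized — diagonal first in
trait order, then the upper triangle row-major, off-diagonals scaled by
$\sqrt 2$ so the Euclidean inner product of vectors equals the Frobenius
inner product of matrices. The $21 \times 21$ sample covariance $S$ of the
vectorized matrices (divisor $m-1$) is eigen-decomposed; eigenvectors map
back to symmetric unit-Frobenius-norm matrices, the eigentensors
$E_1, E_2, \ldots$, of which at most $m - 1$ carry nonzero eigenvalues
$\alpha_i$. The coordinate of matrix $G_j$ in $E_i$ is
$\langle G_j, E_i\rangle$, and the across-set variance of coordinates in
$E_i$ equals $\alpha_i$ exactly — asserted to $10^{-8}$. Each eigentensor is
further decomposed into its own eigenvectors ordered by absolute eigenvalue
(signs matter inside an eigentensor), the first being $e_{11}$. Eigenvalues
$\alpha$ are reported both raw and as proportions of their sum.

Uncertainty is attached by holding the eigentensors fixed at the
point-estimate decomposition and projecting posterior draws of the matrices
onto them, yielding draws of coordinates and of an $\alpha$-analog (the
across-set coordinate variance per draw). Whether to rebuild $S$ per
posterior draw or project onto fixed eigentensors was an open design
choice; projection was implemented because it keeps the eigentensor basis
interpretable across draws and is directly testable (degenerate posteriors
collapse to the point estimate). A fully Bayesian re-decomposition per draw
is out of scope.

## The synthetic-data generator

The generator inverts the fitted models, so every estimate can be checked
against known truth:

* State sequences come from exact continuous-time (Gillespie) simulation —
  exponential holding times, embedded-chain jumps — read off at frame
  times. Nothing is approximated at the frame scale.
* Phenotype tables are built as group mean + covariate effects (on centered
  covariates) + line effect + block effect + residual, with line effects
  drawn once per line from $N(0, 2\mathbf{M})$ and shared by that line's
  plates. Ancestor groups carry **zero** line-level deviation: a founder
  has no accumulated mutations, and its genotypic mean is the group
  baseline.
* Defaults mirror the study conditions: 54 N2 and 62 PB306 MA lines, 16
  shared blocks, two plates per line (ancestors in every block), 4 Hz
  frames, and group-mean offsets equal to the reported background
  differences (0.44, 0.37, −0.50, 0.16, 0.05, 0.51) and mutational biases
  (0.010, 0.004, 0.188, 0.199, 0.094, 0.221) on the log scale, applied on
  the natural-log scale on which all analyses run.
* Values the study design does not pin down were chosen once as plausible:
  mutational variances of 0.05 per trait with 0.3 correlations between
  rates sharing a movement state (pleiotropy), block variances of 0.02,
  residual variances of 0.12, covariates as independent normals
  (temperature 20 ± 0.5 °C, relative humidity 50 ± 5%, log density
  6.9 ± 0.2), and small covariate effects. Per-plate track counts and
  durations default to the magnitudes of a tracking movie (about a
  thousand tracks of about a minute) but are configurable.

What passing tests show — and what they do not: the generator draws from
exactly the Gaussian mixed model the pipeline fits, so recovery and
calibration results demonstrate the estimation machinery is correct and
internally consistent. Real tracker data adds misspecification the
generator deliberately omits: non-Gaussian residuals, heteroskedastic
plates, state mis-assignment near the still boundary, object filtering, and
covariate distributions that are anything but independent normals.
Calibration on synthetic data is therefore necessary, not sufficient, for
trusting the same pipeline on empirical tables.

## Problem sizes and limitations

The packaged checks run the multivariate sampler at thousands to tens of
thousands of iterations with 40–100 lines and permutation nulls of ~100
replicates — sizes chosen so a complete calibration sweep runs on a single
core in minutes while keeping Monte Carlo error well inside every asserted
tolerance. Known limitations: no pedigree or relatedness structure beyond
fully inbred lines; rows with missing trait values are rejected rather than
modeled; the nine-rate parameterization including self-transitions is not
supported (self-transition rates are determined by the off-diagonals); and
the angle null in high dimensions is characterized only qualitatively
(greater than 45°, below 90°), which is all the comparison statistics use.
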