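---
title: "Latent instrumental variables for bivariate causal discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent instrumental variables for bivariate causal discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latentiv)
```

## The model

Two correlated one-dimensional series X and Y of common length N are
observed. Exactly one of three structures is assumed to hold: X → Y, Y → X,
or a hidden common cause X ← U → Y. The key idea is that the prior
generating the cause behaves like a latent instrumental variable. Writing
I_X for an instrument of X, the linear-Gaussian working model is

    X = α₀ + α I_X + δ U + ε_X
    Y = β₀ + β X   + γ U + ε_Y

with independent noises and, in the chain case, δ = γ = 0. An instrument
influences the effect only through the cause, so the instrumented chain
I_X → X → Y implies the testable signature **I_X ⫫ Y | X**: conditioning on
X blocks the only path from I_X to Y. The mirrored statement fails —
conditioning on Y (a collider child in the reverse factorization) leaks X
information into any instrument built for Y jointly with X. Equivalently, in
a mixture of two populations that share one mechanism P(Y|X) but differ in
P(X), the population label is conditionally independent of Y given X, while
the reverse conditional P(X|Y) shifts across populations. The decision tree
is therefore:

1. test Y ⫫ I_X | X; a p-value above α concludes **X → Y** (the backward
   test never runs);
2. otherwise test X ⫫ I_Y | Y; a p-value above α concludes **Y → X**;
3. if both reject while X and Y are correlated, no instrumented chain is
   consistent with the data and a **hidden common cause** is declared. This
   rests on the working assumption that both conditional independences
   cannot hold simultaneously for correlated series.

A forced-choice variant, for benchmarks whose ground truth is always
directional, computes both p-values and answers X → Y iff
p_forward > p_backward (exact ties go to X → Y with a warning). Which rule a
published benchmark number corresponds to is generally not knowable, so both
are first-class and the scoring default is the three-way tree, with
common-cause verdicts counted as errors against a directional truth.

## Approximating the instruments

The instruments are never observed; under the cluster assumption (points in
the same cluster likely share a latent state) they are approximated by
k-means cluster-center series: `cluster_1d()` replaces each observation by
the center of its cluster of X alone (I_XX) or Y alone (I_YY);
`cluster_2d()` clusters the standardized pairs jointly and projects the
assigned centers back onto each coordinate (I_XXY, I_YYX). The selection
step compares

    d_x = dist(I_XX, I_XXY),   d_y = dist(I_YY, I_YYX)

and keeps I_X = I_XX, I_Y = I_YYX when d_x < d_y (branch `x_simpler`), else
I_X = I_XXY, I_Y = I_YY. The rationale is minimum-description-length-like:
if adding Y barely changes how X clusters, X's generative structure is
self-contained and X is the better cause candidate. Ties (exactly equal
distances, as with identical inputs through the same seed path) fall to the
`y_simpler` branch by the strict-inequality rule.

Numerical choices, each surfaced as configuration rather than presented as
intrinsic to the method:

* **Standardization.** X and Y are z-scored before joint clustering and
  before the distance comparison; centers are mapped back to original units
  for storage. Comparing d_x (in X units) against d_y (in Y units) is
  meaningless otherwise, and the branch must not change when X is expressed
  in different units. Each instrument series carries its source variable's
  mean/sd so `select_instruments()` can standardize; bare series fall back
  to the pooled sd of the two series being compared.
* **Distance.** Root-mean-square difference over the N per-observation
  center values — Euclidean, normalized by √N so samples of different sizes
  are comparable.
* **k-means protocol.** k-means++ seeding, 10 restarts, Lloyd iterations,
  best within-cluster sum of squares; ties keep the earliest restart.
  Restarts ending with an empty cluster are discarded; if all do, k is
  decremented with a warning. k is capped at the number of distinct values.
  All of it is seeded and deterministic.

## Choosing k

k is the number of modalities the latent instrument is assumed to have. For
benchmark-style continuous data the default is k = 15; taking very few
(2–3) or very many (70–100) clusters degrades real-data performance, and in
applications k would be fixed by grid search. For the shipped simulations
the instrument is generated with three levels, and there the matched choice
k = 3 is essential, not cosmetic: the branch asymmetry lives at the modal
scale. At k = 15 the micro-clusters segment each mode, the joint clustering
perturbs X's and Y's partitions about equally, and the branch degenerates to
a near coin flip (≈0.63 toward the correct branch in our measurements),
while at k = 3 it is correct in essentially every seed. The package's
simulation experiments (including the acceptance script and the synthetic
benchmark) therefore run with k = min(15, number of instrument modalities).

## The conditional-independence tests

**Continuous.** First-order partial correlation
r = (r_ab − r_ac r_bc)/√((1−r_ac²)(1−r_bc²)), referred to a t distribution
via t = r √(df)/√(1−r²) with df = n − 3 (two-sided). Degenerate conventions,
in precedence order: exactly collinear a and b return their plain
correlation (conditioning cannot break a perfect dependence); a variable
that is an exact linear function of the conditioning series has zero
residual variation and the partial correlation is defined as 0 (evidence of
conditional independence, not dependence); a constant conditioning variable
degrades to the marginal test with df = n − 2 and a warning. Rows with any
missing value are dropped first, and at least 8 complete rows are required
(df ≥ 5).

**Discrete.** G = 2N·CMI(a;b|cond) with the conditional mutual information
in nats from the empirical three-way table (0·log 0 := 0), referred to a
chi-square with df = Σ_s max(0, (r_s−1)(c_s−1)), counting only rows and
columns with nonzero marginals within each stratum; a table whose adjusted
df is 0 is rejected as degenerate. The nats/G-statistic convention is this
package's choice — the asymptotic mutual-information test family it
implements does not pin down the base, and the chi-square reference absorbs
the factor.

One subtlety is deliberate: when the selected I_X is a deterministic step
function of X (centers of X alone), I_X ⫫ Y | X holds exactly as a
distributional statement, yet the finite-sample linear test retains
informative signal because the step function is not linear in X. The
implementation must not — and does not — special-case functional dependence
(e.g. by returning p = 1 when I_X = f(X)); the test is computed identically
for every instrument source.

## The ensemble

`ensemble_infer()` permutes the rows (seeded), splits them into k near-equal
folds (default 10), reruns clustering + selection + testing independently
per fold with fold-local sub-seeds (no information crosses folds), and takes
a majority vote. Its value is variance reduction: under the three-way tree a
single-shot verdict flips whenever the forward p-value crosses α — roughly
an α-sized event even when the direction is clear — whereas a majority of 10
folds almost never flips. Vote ties are broken by the sign of the summed
per-fold p-value difference, the same evidence the forced rule uses, with
preference going to the favored direction, then the other direction, then
the common-cause verdict. Inside the ensemble both p-values are always
materialized per fold (the tie-break needs them); single-shot
`infer_direction()` keeps the short-circuit and reports no backward p-value
on the first branch.

## The simulators and what they do (not) emulate

* `simulate_continuous()` — the linear-Gaussian model above. Defaults:
  α₀ = β₀ = 0, α = β = 1, σ_x = σ_y = 0.5, I_X uniform on {−2, 0, +2}
  (trimodal, so the cluster assumption holds and constructed instruments
  can recover it), U ~ N(0,1) with δ = γ = 1 and β = 0 in the confounded
  scenario. The Y equation carries an optional own-instrument term
  `alpha_y · I_Y`: the confounded and mirrored scenarios need an oracle
  I_Y, which the bare two-equation model does not generate. The default
  chain generates no I_Y edge; its backward instrument is the
  joint-clustered candidate, as in the constructed pipeline.
  `chain_y_to_x` is generated by mirroring, guaranteeing exact symmetry.
* `simulate_discrete()` — binary ancestral sampling on
  I_X → X → Y ← I_Y (chain) or I_X → X ← U → Y ← I_Y (confounded), with
  0.2/0.8-style CPT asymmetries chosen so the conditional-independence
  structure is visible at moderate n. The published experiments do not
  print their CPTs or coefficients; these defaults are this package's,
  chosen once to reproduce the qualitative p-value-versus-n behavior.
* `simulate_mixture()` — two populations sharing one mechanism
  Y = X + N(0, 0.5), with population-specific cause distributions
  P: N(−2, 1) and Q: N(+2, 0.5). The populations differ in location and
  scale deliberately: with equal scales both reverse regressions have the
  same slope Var(X)/Var(Y) and the anticausal asymmetry hides entirely in
  the intercepts, so the slope diagnostic would be blind. That
  equal-variance blind spot is a genuine limitation of slope-based checks,
  not of the mixture argument itself.

These generators emulate the study conditions — discrete-level instruments,
Gaussian noise, linear mechanisms, well-separated clusters. Real data are
none of these: mechanisms are nonlinear, cause distributions need not
cluster, noise is heteroscedastic, and k must be guessed. Passing the
simulation suite therefore demonstrates correctness of the machinery and
the qualitative asymmetries, not real-world accuracy; the real benchmark
is an external download and deliberately outside the test suite.

## Problem sizes and experiment design

The shipped experiments use: 1000 replicates at n = 1000 for null
calibration of the forward test (band 3–7% at α = 0.05); 200 replicates at
n = 5000 for the chain's p-value asymmetry; 100 replicates at n = 5000 for
confounder detection with oracle instruments; 100 replicates at n = 1000
for end-to-end recovery with constructed instruments plus the mirrored
rerun; n = 10000 for the discrete-chain stratum comparison; 100 seeds at
n = 2000 for the mixture label test; and 100 paired replicates of a
marginal-strength chain (β = 0.5, σ_y = 0.8, n = 1000) for the
ensemble-versus-single-shot stability comparison. The marginal-strength
setting is chosen so single-shot verdicts actually flip between replicates;
on a saturated scenario both arms are trivially stable and the comparison
is vacuous.

## Known limitations

* Only bivariate problems; conditioning sets never exceed one variable.
* The continuous test is linear: nonlinear conditional dependence that is
  uncorrelated after linear residualization is invisible to it.
* The branch criterion needs the cluster assumption; on unimodal or
  heavy-tailed causes the distance comparison carries little signal, and k
  far from the latent modality degrades it (see "Choosing k").
* The common-cause verdict inherits the α threshold: weak confounding at
  small n is routinely misread as a direction.
* k-means is the only clusterer shipped, though the construction is
  pluggable by replacing the candidate builder.
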