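# latentiv

Bivariate causal discovery with latent instrumental variables: given two
observed numeric series X and Y, decide **X → Y**, **Y → X**, or **hidden
common cause**.

## The problem and the method

Conditional-independence methods for causal structure learning cannot orient
a single edge: X → Y and Y → X are Markov equivalent. Methods built on the
independence of cause and mechanism can, by asking whether P(X) carries
information about P(Y|X). This package implements a reconciliation of the two
views: if X causes Y, the prior that generated X behaves like a latent
instrumental variable I_X — a variable that influences Y only through X — and
its trace is testable with ordinary conditional-independence tests:

* if I_X exists with I_X → X and I_X ⫫ Y | X, the only consistent directed
  graph is I_X → X → Y, so **X → Y**;
* symmetrically, I_Y ⫫ X | Y supports **Y → X**;
* if X and Y are correlated but both tests reject, no instrumented chain
  explains the data and a **hidden common cause** U is inferred.

The instruments are not observed. Under the cluster assumption (points in the
same cluster likely share a latent state) they are approximated by k-means
cluster-center series: each observation is replaced by the center of its
cluster, built from X alone (I_XX), from Y alone (I_YY), and from both
jointly (I_XXY, I_YYX). A simpler-model criterion picks the pair actually
used: with d_x = dist(I_XX, I_XXY) and d_y = dist(I_YY, I_YYX) (root mean
square over observations, on the standardized scale), d_x < d_y means Y
barely influences how X clusters, so I_X = I_XX and I_Y = I_YYX; otherwise
I_X = I_XXY and I_Y = I_YY.

Two test families are provided, both conditioning on a single variable:

* continuous — the exact t-test for the first-order partial correlation
  r_{ab·c}, with t = r √(n−3) / √(1−r²);
* discrete — a G-test of conditional mutual information, G = 2N·CMI(a;b|c)
  in nats, referred to a chi-square whose degrees of freedom drop
  zero-margin rows and columns per stratum.

Large p-values indicate conditional independence; the decision threshold is
α = 0.05. A forced-choice variant answers sign(p_forward − p_backward) when a
benchmark demands a binary direction, and a seeded k-fold ensemble (default
10 folds) runs the whole pipeline per fold and takes a majority vote.

## Worked example

```r
library(latentiv)

# a trimodal instrumented chain X -> Y, n = 1000
cfg <- continuous_scm_config("chain_x_to_y", n = 1000, seed = 42)
sim <- simulate_continuous(cfg)

# approximate the instruments (k matched to the instrument's 3 modalities)
pair <- approximate_instruments(sim[, c("x", "y")], k = 3, seed = 7)
pair
#> Instrument pair: branch x_simpler (dist_x = 0.2205, dist_y = 0.3153)
#>   IX from x_only, IY from joint_y

infer_direction(sim[, c("x", "y")], pair$ix, pair$iy, test = "continuous")
#> Causal verdict: X -> Y
#>   p(Y ind. IX | X) = 0.4704
#>   p(X ind. IY | Y) not computed (tree short-circuited)
```

The branch says the joint clustering barely moved X's centers
(d_x = 0.221 < d_y = 0.315): X's structure does not need Y, which is the
simpler-model signature of X → Y. The forward test's large p-value (0.470)
then confirms Y ⫫ I_X | X, and the tree stops without running the backward
test. On a confounded simulation both tests reject and the verdict becomes
`hidden common cause`.

Pair files in the two-column cause-effect-pairs dialect are read with
`read_pair_file()`; a labelled directory is scored with `load_benchmark()` +
`evaluate_benchmark()` (weighted and unweighted accuracy, with the standard
multivariate exclusions 52–55, 70–71, 81–83 applied by default). A CLI wraps
the same functions:

```sh
Rscript inst/cli/latentiv infer pair0001.txt --k-clusters 15 --folds 10 --json
Rscript inst/cli/latentiv simulate chain-continuous --n 100,1000 --reps 20 --out rec.csv
Rscript inst/cli/latentiv benchmark pairs/ pairs/pairmeta.txt --out report
```

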