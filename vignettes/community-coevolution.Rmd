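---
title: "Modelling gene coevolution from phylogenetic profiles with phyloCCM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling gene coevolution from phylogenetic profiles with phyloCCM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

A phylogenetic profile records the presence (1) or absence (0) of a gene
across a set of genomes related by a rooted phylogeny. Genes that are gained
and lost together — because they act in one pathway, sit on the same mobile
element, or are otherwise functionally coupled — leave correlated profiles.
The difficulty is that the genomes are not independent observations: close
relatives share gene content for purely phylogenetic reasons, so naive
similarity scores (Jaccard, Hamming, mutual information, hypergeometric
tests) over-count co-occurrences concentrated in a single clade.

phyloCCM models a set of $n$ genes (a *community*) as a continuous-time
Markov chain on the $2^n$ joint presence states, evolving along the tree.
Writing the state of gene $k$ as a spin $x_k \in \{-1, +1\}$ (absent,
present), the instantaneous rate at which gene $k$ flips while the community
sits in state $x$ is

$$\tau_k(x) \;=\; \exp\!\Big(\alpha_k \;-\; \beta_{kk} x_k \;-\;
  \sum_{h \neq k} \beta_{hk}\, x_k x_h\Big),$$

with three kinds of parameters:

* $\alpha_k$ — the *intrinsic rate*, the log-scale mean of gene $k$'s gain
  and loss rates per unit branch length (log gain $= \alpha_k +
  \beta_{kk}$, log loss $= \alpha_k - \beta_{kk}$);
* $\beta_{kk}$ — half the log-scale gain/loss asymmetry;
* $\beta_{hk} = \beta_{kh}$ — the *interaction coefficient* between genes
  $h$ and $k$: positive values slow any transition that would break
  agreement between the two genes (coordinated presence/absence), negative
  values favour disagreement.

The rate matrix $Q$ over joint states assigns $\tau_k(x)$ to every
single-gene flip and zero to simultaneous changes. Because the rates derive
from a potential, the chain is reversible with the closed Ising-form
stationary law $\pi(x) \propto \exp(\sum_k \beta_{kk} x_k + \sum_{h<k}
\beta_{hk} x_h x_k)$, independent of the $\alpha$'s — `ccmStationary()`
exposes it, and the package's tests use the detailed-balance identity as a
strong correctness oracle against the numerically computed null space of
$Q$.

## Likelihood and inference

`pruneLoglik()` computes the likelihood of observed profiles by
Felsenstein's pruning recursion over the joint state space: tip partials are
indicators of the observed joint state, each internal node multiplies its
children's branch-propagated partials, and the root sums against a prior.
The sum over root states is taken against a uniform prior by default
(`"stationary"` and `"fixed"` are available); the interaction estimates are
insensitive to this per-state constant, but reported log-likelihood values
do depend on it. Numerical choices worth knowing:

* branch propagation goes through the eigendecomposition of the
  symmetrized rate matrix $D Q D^{-1}$, $D = \mathrm{diag}(\sqrt{\pi})$
  (valid because the chain is reversible), applied as matrix–vector
  products — transition matrices are never formed, which keeps community
  fits of size 5 (a $32 \times 32$ state space) fast;
* non-reversible generators (the Pagel baseline models) use a general
  eigendecomposition with a scaling-and-squaring fallback when the
  eigenvector basis is ill-conditioned;
* partial likelihoods are rescaled at every node with accumulated log
  scalers, so trees with many hundreds of tips do not underflow;
* zero-length branches propagate the identity.

`fitCCM()` minimizes the penalized negative log-likelihood
$-\log L + \lambda \lVert\Theta\rVert_2^2$ over the $n + n(n+1)/2$ free
parameters with `nlminb` under box constraints $|\theta| \le 10$, starting
from the neutral model $\Theta = 0$ with jittered restarts (3 by default,
jitter sd 0.1; the optimizer tolerances are `rel.tol = 1e-9`, 2000
evaluations). Standard errors come from the central-difference Hessian of
the unpenalized objective (relative step $10^{-4}$); `waldTest()` reports
two-sided Z-tests of each parameter against zero (the sign of
$\hat\beta_{hk}$ carries the direction of the interaction);
`bootstrapSE()` offers the parametric-bootstrap alternative, dropping (and
logging) non-convergent replicates.

The ridge penalty is not a sparsity device. On occasional datasets —
near-perfectly codistributed profiles are the canonical case — the
likelihood surface develops a flat ridge and estimates *overshoot* to
extreme values. `autoLambda()` implements the working rule: fit with
$\lambda = 0$, and only if the condition number of the (penalized) Hessian
exceeds 200 walk up a small grid (0.01, 0.1, 0.5, 1, 2, 5, 10) until it
drops below that threshold. Most analyses never leave $\lambda = 0$. The
rule is a diagnostic heuristic, not a guarantee: a ridge can present a
condition number below 200 at a degenerate optimum (see *Limitations*).

## The simulator

`simulateBranch()` implements the event-driven procedure literally: at the
current state compute every gene's rate, draw each gene's waiting time from
its exponential law, flip the gene with the minimal waiting time if it fits
in the remaining branch length, subtract, repeat. Resampling all clocks
after every event is statistically equivalent to the classical Gillespie
scheme by memorylessness; the tests check the event count against its
Poisson law and the end-state distribution against $\exp(Qb)$ in total
variation. `simulateProfiles()` draws a root state from the stationary law
(the conventional choice, avoiding transient bias; a fixed root is
available) and walks the tree root-to-tips.

Scenario generators reproduce the benchmark designs used throughout the
package's evaluation:

* `genBenchmarkPairs()` — null pairs ($\beta_{12} = 0$) versus interacting
  pairs ($\beta_{12} \sim U(0.2, 0.5)$), each on a fresh random tree;
* `genDarwinPair()` — a single concurrent origin: both genes present on
  exactly the tips of one uniformly chosen internal clade (optionally with
  flip noise), the textbook case of within-clade pseudoreplication giving
  perfect correlation but weak evidence of coevolution;
* `genReplicatedPair()` — the same number of co-occurrences spread
  non-monophyletically across the tree, the strong-evidence counterpart;
* `genTopologyCommunity()` — arbitrary interaction graphs (line, star,
  partially and fully connected five-gene structures, the conditionally
  independent chain triplet).

`randomTree()` draws a Yule (pure-birth) topology and rescales branch
lengths to a mean of 0.1, the conventional scale for these comparative
analyses. Defaults elsewhere follow the neutral symmetric model
($\alpha = 0$, $\beta_{kk} = 0$) so that simulated effects are attributable
to the interaction coefficients alone.

What the generator does *not* emulate matters for interpreting results:
real profile collections have unbalanced, non-Yule trees (oversampled
pathogen clades), homology-calling noise, copy-number variation collapsed
to presence/absence, and lateral transfer that correlates genes with
*lineages* rather than with each other. Passing the simulation benchmarks
shows the estimator recovers its own generative model on trees of the
stated size — not that every real-data inference is safe.

## Baselines and the network pipeline

For comparison the package ships the standard scores (`jaccardIndex()`,
`basicScores()` for Hamming, mutual information and the upper-tail
hypergeometric test) and their phylogeny-aware adjustments:
`cladeAdjustedScore()` collapses every maximal clade whose tips share one
joint pattern into a single pseudo-genome; `runAdjustedScore()` collapses
maximal runs of identical joint patterns in the tree's deterministic
left-to-right tip order. Both operationalizations reconstruct one-sentence
descriptions from the comparative-methods literature; the collapsed-table
hypergeometric is used as the test statistic because it was the strongest
of the candidate metrics in our benchmarks. `pagelLRT()` fits the classical
pairwise correlated-evolution test — a 4-rate independent model against an
8-rate dependent model on the four joint states, $\chi^2_4$ likelihood
ratio — on the same pruning kernel with a uniform root prior and rates
capped at 100 (the conventional bound). Under independence the 4-state
likelihood factorizes, so the independent model is fitted as two 2-state
chains and the dependent fit starts from those estimates.

`pairwiseScan()` fits every gene pair (deterministic per-pair seeds derived
from a master seed, so parallel or reordered execution cannot change
results), applies the Benjamini–Yekutieli correction — valid under the
arbitrary dependence these tests exhibit — and `buildNetwork()` keeps edges
passing both $\hat\beta > 0.75$ and $Z > 7.5$ by default.
`tripletPrune()` then re-fits every edge jointly with each adjacent third
gene and removes edges that become weakly significant in its presence
($p > 0.001$ and $\hat\beta < 0.5$): conditionally independent links that
pairwise testing cannot distinguish from direct ones. An edge is pruned
when at least one conditioning gene condemns it (the default; a strict
all-triplets mode is available), and the report records which gene
explained each removed edge away.

## A worked example

```{r example, eval = FALSE}
library(phyloCCM)

tree <- randomTree(100, seed = 2)
truth <- ccmParams(alphas = c(0, 0),
                   beta = matrix(c(0, 0.5, 0.5, 0), 2))
set.seed(2)
profiles <- simulateProfiles(tree, truth)

fit <- fitCCM(tree, profiles, seed = 2)
waldTest(fit)
```

The interaction row (`beta_12`) is the quantity of interest: its estimate
recovers the simulated coupling up to sampling noise, and its Wald test
answers "do these two genes interact given the tree?".

## Study designs and problem sizes

The package's acceptance checks re-run the simulation studies at these
sizes, chosen to keep a full run comfortable on one CPU:

* pair benchmark: 500 null + 500 interacting pairs, each on a fresh
  100-tip Yule tree (mean branch length 0.1); group means of
  $\hat\beta_{12}$, and the ROC panel over the community Wald statistic,
  the Pagel LRT, the run- and clade-adjusted hypergeometric scores and the
  Jaccard Index;
* single-origin vs replicated codistribution: 100 tree replicates, fits
  through the condition-number rule (`autoLambda()`), comparing mean
  intrinsic-rate estimates and Z-score distributions;
* conditionally independent triplets ($\beta_{13} = 0.5$, $\beta_{23} =
  0.8$, $\beta_{12} = 0$): 100 replicates; the community fit's p-values on
  the absent edge against uniformity, the pairwise Pagel flag rate at
  0.05;
* five-gene structures (line, star, partial, full; all edges at 0.5): 48
  replicates per structure, single-start fits, on 300-tip trees — a
  20-parameter joint fit needs substantially more information than a
  pairwise one, and at 100 tips the five-gene model is unidentifiable in
  practice; medians of edge and non-edge estimates are compared to the
  truth.

## Design choices where the ground was open

* **State coding** — gene $k$ occupies bit $k-1$ of the state index
  (little-endian); every module shares this convention.
* **Root prior** — uniform by default; the stationary option exists, and
  fixing the root supports single-origin constructions.
* **Penalty scope** — the ridge covers the full parameter vector including
  $\alpha$'s and diagonal $\beta$'s; no intercept exemption.
* **Two-sided tests** — interactions are tested without a prior direction;
  the sign is reported separately.
* **Tip order** — the deterministic left-to-right (cladewise) order of the
  written Newick string, so "consecutive genomes" in the run-adjusted
  score is well defined and mirror-invariant.
* **Frequency filter** — `filterByFrequency()` removes genes strictly
  below 1% or strictly above 99% presence; boundary-equal genes stay.
* **Capacity guard** — community fits refuse $n > 12$ by default; the
  state space grows as $2^n$ and joint fits beyond ten genes are better
  approached through the pairwise-scan + triplet-prune pipeline.

## Limitations

* The condition-number rule can miss degenerate optima: perfectly
  codistributed pairs (the single-origin construction) produce a ridge
  along which $\alpha + \beta_{12}$ inflates jointly while the Hessian
  still reports a condition number below 200. Estimates of $\beta_{12}$'s
  *significance* remain usable; absolute intrinsic-rate estimates on such
  degenerate profiles depend on where the optimizer comes to rest and
  should be read qualitatively (low for single-origin, high for
  replicated patterns).
* Statistical power and estimator dispersion depend strongly on the
  information content of the tree (its size and total length). Results
  from 100-tip simulated trees are not directly comparable to analyses on
  phylogenies several times larger.
* Missing or ambiguous tip states are rejected rather than marginalized;
  profiles must be complete 0/1 matrices.
* The pruning cost is linear in tips but exponential in community size;
  the scan pipeline stops its automated conditional-independence pruning
  at triplets (the API accepts larger communities up to the guard).
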