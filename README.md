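# phyloCCM

Joint modelling of correlated gain and loss of binary traits — phylogenetic
profiles — on a rooted phylogeny.

## The problem

A phylogenetic profile is a 0/1 vector recording which genomes carry a
gene. Genes that work together tend to be gained and lost together, so
correlated profiles are a classic signal of functional linkage. But genomes
on a tree are not independent samples: closely related genomes share gene
content whether or not any two genes interact, and naive similarity scores
(Jaccard, Hamming, mutual information, hypergeometric tests) are badly
confounded by clade structure. The canonical failure is *Darwin's
scenario*: two genes gained once on the same lineage and inherited by an
entire clade are perfectly codistributed yet provide essentially one
observation of coevolution, not hundreds.

phyloCCM addresses this with an explicitly evolutionary model. A set of
genes analysed together (a *community*) evolves as a continuous-time Markov
chain over the $2^n$ joint presence states. With gene $k$'s state written
as a spin $x_k \in \{-1, +1\}$, its instantaneous flip rate in community
state $x$ is

$$\tau_k(x) = \exp\Big(\alpha_k - \beta_{kk} x_k - \sum_{h \ne k} \beta_{hk} x_k x_h\Big),$$

where $\alpha_k$ is the gene's intrinsic rate (log-scale mean of gain and
loss rates per unit branch length), $\beta_{kk}$ half the log gain/loss
asymmetry, and the symmetric $\beta_{hk}$ are interaction coefficients:
positive values slow transitions that break agreement between genes $h$
and $k$, negative values favour disagreement. The likelihood on a tree is
computed by Felsenstein's pruning algorithm; fitting maximizes an
$\ell_2$-penalized likelihood by quasi-Newton, with Wald Z-tests of
$\beta_{hk} = 0$, parametric-bootstrap standard errors, and a
condition-number rule for choosing the penalty on the rare ill-conditioned
datasets. Modelling three or more genes jointly distinguishes direct
interactions from pairwise associations that are conditionally independent
given a third gene — the basis of the package's network-pruning pipeline.

The package also ships the simulator used to benchmark such methods
(event-driven gain/loss along every branch, plus generators for
null/interacting pairs, single-origin vs replicated codistribution, and
arbitrary interaction-graph communities) and the standard baselines
(Jaccard, Hamming, mutual information, hypergeometric, run- and
clade-adjusted variants, and Pagel's independent/dependent likelihood-ratio
test).

## A worked example

```r
library(phyloCCM)

tree <- randomTree(100, seed = 2)                # 100-tip Yule tree
truth <- ccmParams(alphas = c(0, 0),
                   beta = matrix(c(0, 0.5, 0.5, 0), 2))
set.seed(2)
profiles <- simulateProfiles(tree, truth)        # coevolved 0/1 profiles

fit <- fitCCM(tree, profiles, seed = 2)
waldTest(fit)
#>   parameter   estimate        se          z           p
#> 1   alpha_1  0.7211293 0.4522420  1.5945650 0.110809541
#> 2   alpha_2  0.2707928 0.5681377  0.4766324 0.633623894
#> 3   beta_11 -0.3761814 0.2749869 -1.3679973 0.171312928
#> 4   beta_12  0.5903954 0.2210664  2.6706699 0.007570006
#> 5   beta_22 -0.2743204 0.4270742 -0.6423249 0.520662251
```

The `beta_12` row is the interaction between the two genes: the estimate
0.59 recovers the simulated coupling of 0.5 within its standard error, and
its Wald test (p = 0.0076) correctly reports a significant positive
interaction. The `alpha` rows say both genes flip at roughly rate
$e^{0.3}$–$e^{0.7}$ per unit branch length; the diagonal `beta_11`,
`beta_22` rows report no significant gain/loss asymmetry — all consistent
with the neutral intrinsic parameters used in the simulation.

For many genes, `pairwiseScan()` fits every pair and applies the
Benjamini–Yekutieli correction, `buildNetwork()` thresholds the result into
a coevolution graph, and `tripletPrune()` removes edges that a third gene
explains away.

A thin command-line front end over the same functions is installed at
`inst/cli/ccm.R` (subcommands `fit`, `simulate`, `benchmark`, `baseline`,
`scan`, `prune`, `roc`).

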