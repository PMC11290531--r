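---
title: "Detecting shifts in equilibrium base composition on a phylogeny"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting shifts in equilibrium base composition on a phylogeny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`compshift` fits nonstationary nucleotide substitution models in which the
equilibrium base frequencies $\pi = (\pi_A, \pi_C, \pi_G, \pi_T)$ are allowed
to change at a small number of edges of a fixed, rooted phylogram. A
*regime* is a contiguous set of branches sharing one frequency vector; a
*shift* starts a new regime on the branch subtending an internal node (the
stem-edge convention) and applies to everything below it, unless overridden
by a nested shift. The root carries the ancestral regime.

Within every regime the process is a reversible GTR-family model
$Q_{ij} = s_{ij}\,\pi_j$ with exchangeabilities $s_{ij}$ (HKY with a single
transition:transversion parameter $\kappa$ by default, full GTR optionally)
shared across the whole tree; only $\pi$ differs among regimes. Each
regime's rate matrix is rescaled to one expected substitution per unit
branch length under its own frequencies, so the input branch lengths retain
their units (expected substitutions per site) everywhere on the tree. The
concatenation of regimes along a root-to-tip path makes the process
nonstationary: observed tip compositions drift toward each regime's
equilibrium at a rate set by the local branch lengths, and clades that have
not yet equilibrated are informative about both the old and the new
composition.

Likelihoods are computed by Felsenstein's pruning algorithm over
pattern-compressed alignment columns, with the transition matrix on the
branch into node $x$ built from the frequencies of $x$'s regime and the root
partials weighted by the ancestral regime's frequencies. Site-rate
heterogeneity uses the standard mean-per-category discretized gamma
distribution (categories averaged with equal weights). Gaps, `N`, `?`, and
IUPAC ambiguity codes enter as partial-likelihood rows (fully missing
symbols contribute a vector of ones), the conventional treatment for data
the model does not resolve.

## The search

Shift placement follows a stepwise, information-criterion-guided procedure:

1. Fit the homogeneous model by joint maximum likelihood: root composition,
   exchangeabilities, and (if enabled) the gamma shape. These nuisance
   values are then held fixed during the search.
2. Visit every *eligible* internal node (non-root, clade of at least
   `min_clade` leaves; default 4) in postorder and fit a two-regime model:
   the clade's composition free, the rest of the tree at the root
   composition.
3. Score each candidate by BIC, $k\ln n - 2\ln L$, with $k$ counting three
   free frequencies per regime plus the shared nuisance parameters and $n$
   the number of alignment sites (a flag substitutes unique patterns).
4. Order candidates by ascending BIC; starting from the root-only model,
   tentatively add each candidate, re-estimate compositions, and accept the
   shift only if the updated BIC is strictly lower.

Step 4's re-estimation depth is configurable (`refit`):

* `"all"` (default) re-optimizes every regime jointly at each trial by
  coordinate ascent over regimes (newest first, ancestral last; up to 5
  sweeps, stopping when a sweep gains less than `tol = 1e-6` log units).
* `"new"` re-estimates only the candidate's composition against the current
  configuration during a trial, and runs the full joint re-optimization once
  a shift is accepted. Every comparison therefore pits a jointly fitted
  current configuration against a lower bound of the trial's joint
  likelihood, which makes acceptance conservative rather than permissive.
  This is the mode the package's own simulation benchmarks use: it is an
  order of magnitude cheaper than `"all"` on hundred-replicate grids and,
  in our calibration experiments, accepts the same configurations.
* `"none"` keeps the candidate's single-shift estimate verbatim (the
  literal reading of the stepwise rule). We found this mode degenerate once
  a true shift is in the configuration: compositions frozen against a
  root-only background systematically mis-state the joint BIC and admit
  overlapping spurious shifts. It is retained for comparability only.

Support for each accepted shift is summarized by BIC weights: an
*existence* weight comparing the final configuration against the same
configuration with the shift removed (compositions refit), and *location*
weights over the focal node and its internal daughters. Leaf daughters
cannot host a clade shift and are excluded with renormalization. Weights
are reported, never used to delete shifts automatically; an optional
`prune_below` threshold applies the weight-based filter explicitly.

### Numerical choices

Composition optimization runs on softmax-transformed frequencies with
L-BFGS-B. The homogeneous nuisance fit and candidate scoring use a
convergence factor that resolves the log-likelihood to roughly $10^{-3}$
of a unit — two orders of magnitude below any BIC penalty involved — while
coordinate-ascent refits use a tighter factor so that the sweep-level
$10^{-6}$ stopping rule is detectable. Optimizer starts are deterministic:
empirical base counts of the relevant taxon subset (weighted through the
ambiguity contrast matrix), or the current estimates when warm-starting.
Random restarts are available (`n_starts`) and seeded.

Transition matrices come from the symmetrized eigendecomposition of each
regime's rate matrix; partial likelihoods are rescaled per node and pattern
to avoid underflow on deep trees. Refitting one derived regime only
recomputes the nodes whose subtree intersects that regime's branches, and
for clades containing at most half the tips the likelihood is factorized
through the shift node: an outside vector at the stem (fixed during the
refit) is combined with inside partials computed on the clade's
deduplicated sub-patterns. The factorized and full-tree evaluations agree
to ten significant digits (tested), so the choice is purely a matter of
speed. Ties in candidate ordering break by postorder index; the search is
deterministic given data and settings.

Branch lengths are never re-optimized and are not counted in $k$: the
method conditions on a phylogram estimated upstream. Nuisance parameters
are estimated once under the homogeneous model. The latter is a deliberate
bias-variance trade: on strongly shifted data a single shared $\kappa$
fitted homogeneously is slightly misspecified, and we observe that this can
admit additional regimes that soak up the misfit (see Limitations).

## The simulation framework

`simulate_dataset()` generates validation data matching the search's model
family: shift nodes sampled under clade-size, buffer, and lineage
constraints; regime and root compositions drawn from a Dirichlet; sequences
evolved site-independently under HKY with the stem-edge convention.

Defaults mirror the validation conditions the package is calibrated
against: minimum clade size 4, maximum clade size three quarters of the
tips, a buffer of two edges between selected nodes, independent or nested
configurations, $\kappa = 2$ (the rate-parameter reading of a 2:1
transition:transversion setting), uniform Dirichlet compositions, uniform
site rates, and alignment lengths from 2 to 100 kbp. `generate_toy_tree()`
supplies pure-birth trees scaled to a root-to-tip depth of 0.5 expected
substitutions per site — a generic deep-phylogeny scale chosen once — with
a `burst` mode that compresses the oldest 20% of splits into the top 5% of
depth to emulate an early rapid radiation.

What the simulator deliberately does not emulate: indels and alignment
error, within-regime compositional heterogeneity, heterotachy beyond regime
shifts, selection, and gene-tree discordance in the sequence data. Passing
benchmarks on these data therefore demonstrates that the search is
well-calibrated when its model family is correct, not that real genomes
satisfy that family; on empirical data the existence and location weights,
and the `prune_below` filter, are the guard against over-interpretation.

Benchmark problem sizes in the shipped tests and acceptance script are
desk-scale by design: 100 no-shift replicates at 10 kbp on a 64-tip tree
for the null calibration, and 30 two-shift replicates at 1 kbp on a 250-tip
tree for the false-negative bound. Both run the search as the published
benchmarks of this method family do — no gamma, no weight estimation — with
`refit = "new"`.

## Evaluation statistics

Detections are matched to simulated truth by canonical clade identity (the
sorted set of descendant leaf labels); an optional path-distance tolerance
permits near-miss matching, greedily and one-to-one, closest pairs first.
Per dataset the false-negative rate is the share of simulated shifts not
recovered, and the false-positive rate is reported two ways, since the
normalization of published benchmark tables of this kind is ambiguous: per
eligible non-truth node, and as a binary any-spurious-shift indicator. Mean
rates are tested against zero with one-sided one-sample $t$ and $Z$ tests
(all-zero samples give $p = 1$ by convention; constant positive samples
give $p = 0$ and are flagged) and Benjamini–Hochberg adjustment across the
family of tests.

## Regime summaries

Per-regime outputs compare the fitted equilibrium frequencies with the
empirical frequencies of the regime's taxa. The headline deviation metric
is total-variation distance ($\tfrac12\sum_i |\pi^{eq}_i - \pi^{emp}_i|$,
bounded in $[0,1]$); Euclidean distance and per-base deltas are always
emitted alongside because figure-level "shift magnitude" metrics in this
literature are rarely specified exactly. GC content ($\pi_G + \pi_C$) is
computed from both vectors, and when a body-mass table is supplied the
regime-level regression of GC on mean $\log_{10}$ mass is fit by ordinary
least squares for both responses — the mechanistically interesting
direction being negative under GC-biased gene conversion whose efficacy
grows with effective population size, itself inversely related to body
mass. Clade mean mass is the arithmetic mean of $\log_{10}$ grams over the
regime's taxa.

## Boundary-proximity analysis

To ask whether shifts cluster near a temporal boundary (66 Ma by default),
internal nodes become observations by grafting a negligible-length terminal
($\varepsilon = 10^{-6}$ Ma, sensitivity-adjustable) onto every internal
node of a chronogram; shared path lengths, and hence a phylogenetic
covariance, are then well defined for node-level states. The predictor is
$\ln\max(|\text{stem age} - \text{boundary}|, 10^{-3})$ — proportional
proximity, with a floor for nodes on the boundary. Stem ages (the parent
node's age) are the default; crown ages are available by flag.

Gene-tree discordance enters as an optional covariate: gene-tree nodes
below a support cutoff (default 95) are collapsed, each reference
bipartition is restricted to the taxa shared with a gene tree, and the tree
counts as concordant if it contains the restricted split, conflicting if it
contains an incompatible one, and non-decisive otherwise (including
post-collapse polytomies — a deliberate choice, since a polytomy neither
agrees nor conflicts). The discordance proportion uses decisive trees as
the denominator (an all-informative-trees variant is emitted too) and is
arcsine-square-root transformed. Model predictions are reported at low
(mean − 1 SD), mean, and high (mean + 1 SD) discordance.

The regression itself is a logistic model whose estimating equations carry
a working correlation $R(\alpha) = \exp(-\alpha D)$, with $D$ the patristic
distance matrix scaled to unit maximum — a mean-reverting transform of
shared path lengths in the spirit of phylogenetic logistic regression. The
signal parameter $\alpha$ is estimated by maximizing the Gaussian
pseudo-likelihood of the standardized residuals; $\alpha \to \infty$
recovers ordinary logistic regression exactly (with $R = I$ the estimating
equations are the GLM score equations), which is the package's primary
correctness oracle for this component, together with sign recovery on
simulated node data. Coefficient uncertainty comes from a parametric
bootstrap through a latent-Gaussian copula with correlation
$R(\hat\alpha)$. No installed package implements this estimator for binary
responses, so it is written here at the contract level rather than wrapped;
coefficient-level equality with any particular external implementation is
not claimed.

## Worked example

```{r, eval = FALSE}
library(compshift)

tree <- generate_toy_tree(64, seed = 11, depth = 0.5)
truth <- simulate_dataset(tree, "independent", n_shifts = 2,
                          length = 20000, seed = 42)
fit <- detect_shifts(tree, truth$alignment, gamma_categories = 0,
                     refit = "new")
summary(fit)
match_shifts(tree, truth$shift_nodes,
             node_from_leafset(tree, fit$leafsets))
```

## Known limitations

* Fixed nuisance parameters: $\kappa$ (or GTR rates) and the gamma shape
  are estimated once under the homogeneous model. On data with strong
  composition shifts this estimate is a compromise, and the residual misfit
  can be absorbed by extra regimes — inflating shift counts relative to the
  generating configuration even when every simulated shift is recovered.
  The existence/location weights and `prune_below` are the practical
  mitigation, and `refit_nuisance`/`refit_exch` re-estimate the shared
  parameters at a fixed configuration (which removes the composition bias
  in parameter-recovery experiments); re-estimating them inside every
  candidate trial is deliberately out of scope of the stepwise design.
* The search conditions on the input topology and branch lengths;
  phylogram error propagates into both shift placement and composition
  estimates.
* The greedy procedure explores one path through configuration space;
  configurations whose improvement only materializes jointly (two
  complementary shifts, neither helpful alone) can be missed.
* The boundary regression treats the grafted-tip correlation structure as
  exchangeable with a tip-level trait model; it is a pragmatic device for
  node-level states, not a generative model of shift evolution.
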