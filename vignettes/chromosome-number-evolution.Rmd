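---
title: "Models and statistics for chromosome-number evolution on tree sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and statistics for chromosome-number evolution on tree sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromphylo)
```

## The problem

Haploid chromosome numbers evolve by a small set of mechanisms: dysploid
gain or loss of a single chromosome, duplication of the whole complement
(polyploidy), and demi-duplication (a 1.5-fold increase, e.g. via
triploid bridges). Given counts at the tips of a rooted phylogeny, we
want ancestral counts at internal nodes, the balance of gains versus
losses along the tree, and — crucially — how much those inferences move
when we change the reconstruction method, the branch-length model, the
rate model, or the tree itself within a posterior sample. `chromphylo`
provides each ingredient as a separate, testable function and a driver
(`run_experiment()`) that assembles the full comparison.

## The models

### Dysploidy/polyploidy CTMCs

The state space is the integer interval `[n_min, n_max]`. From count
$i$, the instantaneous rates are

* gain $i \to i+1$ at $\lambda$ (plus $\lambda_1 (i - n_{\min})$ in the
  linear-rate families),
* loss $i \to i-1$ at $\delta$ (plus $\delta_1 (i - n_{\min})$),
* duplication $i \to 2i$ at $\rho$,
* demi-duplication at $\mu$: even $i$ goes to $1.5i$; odd $i$ splits
  $\mu/2$ to each of $\lfloor 1.5i \rfloor$ and $\lceil 1.5i \rceil$.

Events whose target would exceed `n_max` are dropped rather than
redirected, and effective rates driven negative by a linear term are
clamped at zero (with a warning). The eight families are the constant-
and linear-rate crossings of {no duplication, duplication, duplication
with $\mu = \rho$, free $\mu$}; parameter counts run from 2 (`CRND`) to
6 (`LRDE`). The linear term is indexed from `n_min` (the alternative,
indexing from count 1, only reparameterizes the intercept and is not
separately identifiable from these data).

Default bounds when not given: `n_min = max(1, min(observed) - 2)`,
`n_max = 2 * max(observed) + 2`. The lower slack admits ancestral
states slightly below the observed range; the upper bound keeps one
duplication from any observed count inside the space. Bounds are fully
configurable (e.g. pinned to 9 and 12 for truncated-space experiments).

### Ladder and general Mk models

`ORDERED_K` restricts transitions to neighbouring *observed* counts —
on the ladder 9, 10, 11, 12, 14 the neighbours of 12 are 11 and 14 —
with one shared rate, two rates (up/down), or one rate per directed
edge. `FULL_MK` is the general model over the observed counts with all
$n(n-1)$ directed rates, optionally grouped into classes; it is the
model space the reversible-jump sampler explores. For these models a
sampled multi-step move (e.g. 12 to 14) is counted in chromosome units
(two gains), matching the parsimony convention.

### Likelihood and root treatment

`tree_log_likelihood()` is Felsenstein pruning with per-branch
$P(t) = e^{Qt}$, computed by eigendecomposition with a dense Padé
(`Matrix::expm`) fallback when $Q$ is near-defective, cached per unique
branch length; zero-length branches are identity transitions. The root
prior defaults to uniform over the states with nonzero conditional
likelihood at the root; uniform-over-all-states and fixed-state priors
are selectable, since different programs in this area make different
(and rarely stated) choices.

## Reconstruction

`marginal_reconstruction()` returns, for every internal node, the
posterior state distribution conditional on all tips (up–down
algorithm). Rows are keyed by the node's *clade* — the sorted tip set —
so reconstructions from different trees can be aligned on shared clades.

`expected_events()` samples complete histories conditional on the data:
joint node states root-to-tips, then per-branch paths by
uniformization, with the endpoint-conditioned jump count drawn from its
exact Poisson mixture and the embedded chain bridged through cached
powers of the uniformized matrix. Each realized jump is classified by
its labelled rate component (gain, loss, duplication,
demi-duplication); where several components feed one transition the
type is sampled proportionally to their rates. For models whose only
events are unit dysploid steps, the per-branch expected gains minus
losses equals E[child] − E[parent] in expected chromosome number;
`gl_telescoping()` exposes this identity as a cheap cross-check, and it
is also the exact expectation used for ladder/full-Mk G−L in the
experiment driver (no Monte-Carlo error, no duplication events to
count).

Ordered parsimony (`sankoff_ordered()`) uses cost $|i-j|$ over all
integers between the observed extremes, so unobserved intermediates
(13 on the ladder above) are valid ancestral states. `mp_gl()` averages
the signed per-branch change over reconstruction ambiguity in two
modes: per-branch uniform averaging over the product of the two nodes'
MPR sets (default; an approximation, since MPR sets are not jointly
free), and exact enumeration of all joint most-parsimonious assignments
(trees up to 20 tips). Both are reported because fractional G−L values
can arise from either convention and the choice is rarely documented.

## Model uncertainty

`aic_table()` ranks fits by AIC and derives Akaike weights, the
second-best/best weight ratio, and how many models fall outside the
minimal set with cumulative weight 0.95. `model_average()` forms the
weighted arithmetic mean of per-model node distributions.

The Bayesian layer puts independent gamma priors (mean $m$, variance
$v$) on rates with $m, v \sim \mathrm{Uniform}(0,1]$ hyperpriors.
`mcmc_fixed()` mixes log-scale random-walk updates with independence
draws from the current gamma prior (the latter make the flat-likelihood
case an exact Gibbs step) and tunes proposal scales during burn-in
only. `rj_mcmc()` samples the augmented partition space — every
assignment of the directed rates to rate classes plus a possibly-empty
zero class, with a uniform prior over these configurations (a space of
size Bell($n{+}1$)); single-rate reassignment moves create and delete
classes with prior-drawn rates, so the dimension-matching factors
cancel and the acceptance ratio reduces to the likelihood ratio times a
destination-count correction. Marginal likelihoods use the harmonic
mean of posterior likelihoods (log-sum-exp stabilized) because that is
the estimator the surrounding literature reports; it is biased and
high-variance, which is why `log_bayes_factor()` is annotated with the
conventional decision threshold of 2 rather than treated as exact.

One empirical note on the reversible jump: with hierarchical gamma
priors the penalty for splitting a well-fitting rate class is mild, so
the posterior number of classes stays close to its value under the
partition prior even when the data were generated with a single class.
What the data do move decisively is the zero class: rates governing
frequently observed transitions are pulled out of it (their posterior
zero-assignment probability drops far below the prior level), which is
the recovery property the test suite checks.

## Tree-set machinery

Clade identity is the rooted taxon set throughout (the pipeline's trees
are rooted before pruning outgroups, so no unrooted-bipartition
fallback is needed). `majority_consensus(threshold = 0.95)` contains
exactly the clades at or above threshold; `mcc_tree()` scores members
by the sum of log clade frequencies (the product convention; plain sums
selectable) with ties to the lowest index.
`integrate_reconstructions()` averages per-tree node distributions over
the trees containing each target clade. When methods are compared on
one tree set, the precision state union X is built over the union of
the compared reconstructions so that RPₙ values are commensurable;
per-tree distributions are averaged within each tree first and across
trees second.

## Precision statistics

With $C$ the number of states in the union X of states reconstructed
anywhere with probability above the cutoff (default $10^{-2}$),
$\mathrm{RP}_n = (C \max_j P_j - 1)/(C - 1)$ rescales the top
reconstruction probability from its attainable range $[1/C, 1]$ to
$[0, 1]$. When $C = 1$ the formula is 0/0 and the value is defined as 1
(a single reconstructible state is maximal precision). The G−L
distribution over a tree set is summarized by mean, median, raw
min/max range, and the Chernoff mode with bandwidth 0.5: the center of
the width-1 window holding the most trees, scanned over the data
values, consecutive midpoints and window edges $x_i \pm h$ clamped to
the data range (the edge candidates are needed for the window count to
attain its global maximum; ties go to the smallest center).

## Synthetic data

`simulate_counts()` is a Gillespie simulation down every branch that
records each event with its type and endpoints, so truth-based tests
can check bookkeeping exactly. `pseudo_posterior()` emulates a
posterior sample's statistical character — Poisson-distributed rooted
NNI moves plus lognormal branch-length jitter around a signal tree — it
is *not* a substitute for phylogenetic inference and reproduces neither
the correlation structure of real MCMC samples nor alignment-driven
support patterns. The desk-scale bundle
(`melampodium_like_fixture()`) uses a 39-tip Yule tree rescaled to
total length 5 (one unit per ladder state), counts simulated under
`CRND` with gain = loss = 0.4 from root count 11 on states 9–14 (about
two expected events per tree — drifty but informative, like the real
ladder data this emulates), and a 450-tree pseudo-posterior (a 10×
scale-down of the 4,500-tree samples such studies use; tests use
smaller sets still). Passing tests on these data show the machinery is
correct under its own model assumptions; they do not show the models
fit any particular real genus.

## Numerical choices and scale

* Optimizer: L-BFGS-B on log rates in $[10^{-6}, 10^3]$ per unit branch
  length (linear coefficients unconstrained), multi-start with seeded
  jitter; refits with the same seed are bit-identical.
* Transition matrices: rows of $e^{Qt}$ are clipped at zero and
  renormalized (deviations are at rounding level).
* Default chain lengths are desk-scale (tens of thousands of
  iterations); production settings of hundreds of millions of
  generations are reachable through the same arguments.
* `run_experiment()` analyzes an evenly spaced subset of the tree set
  per method (defaults: 25 trees for likelihood methods, 4 for MCMC
  methods, always including the MCC tree) — the problem sizes used by
  the package's own test runs; raise the caps for full analyses.

## Information limits worth knowing

On a tree rescaled to total length 5, a rate of 1 per unit length means
about five expected events of that type on the whole tree, so
single-tree rate estimates carry irreducible Poisson noise of order
$1/\sqrt{5} \approx 45\%$ regardless of tip count; gain/loss *ratios*
and model-averaged reconstructions are far more stable than individual
rates. This is a property of the rescaling convention, not of the
optimizer — parameter-recovery experiments at these settings should be
read with that floor in mind.

## Known limitations

* No base-number (monoploid) transition parameter and no
  branch-heterogeneous rates.
* The harmonic-mean marginal likelihood is retained for comparability,
  not for its statistical merits.
* Consensus trees carry no branch lengths (clade frequencies and
  integrated probabilities are node annotations).
* Joint-MPR enumeration is exponential and capped at 20 tips.
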