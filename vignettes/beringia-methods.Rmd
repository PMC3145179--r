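---
title: "Methods: dating, range evolution, thermal tolerances and the Beringian gateway"
author: "beringia package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dating, range evolution, thermal tolerances and the Beringian gateway}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models behind the package, the choices that were
genuinely open when it was built, and what its tests do and do not show.
The scientific question it serves: did the blues of the *Polyommatus*
section reach the New World through Beringia in several waves, and did the
cooling climate of that corridor filter which lineages could cross?

# Divergence dating

Branch lengths of a phylogram are expected substitutions per site; a
substitution rate $r$ (substitutions · site$^{-1}$ · yr$^{-1}$) converts
path lengths into time. Two estimators are provided.

**Strict clock** (`strict_clock_ages`). The age of a node is the mean
tip-to-node path length over its descendant tips divided by $r$. Averaging
absorbs moderate rate heterogeneity; a final rootward pass clamps any
residual parent-younger-than-child violation. This estimator is linear in
the branch scale, so doubling $r$ halves every age.

**Penalized likelihood** (`pl_smooth_ages`). Node times $t$ and per-branch
rates $r_b$ jointly maximize

$$\sum_b \left[ n_b \log (r_b \Delta t_b) - r_b \Delta t_b \right]
  \;-\; \lambda_s \sum_{b' = \mathrm{parent}(b)} (r_b - r_{b'})^2 ,$$

a Poisson likelihood of expected substitution counts
($n_b = \text{branch length} \times \texttt{sites}$) minus a smoothness
penalty on rate changes between adjacent branches (the root's child
branches are penalized pairwise). Without fossil calibrations the time
scale is fixed by pinning the arithmetic mean branch rate to the configured
$r$. The optimizer is BFGS on log root age, logit age proportions and log
relative rates, multi-started from two analytic points — the strict-clock
solution and an ages-only fit with all rates pinned equal — plus seeded
perturbations. The second start makes the large-$\lambda_s$ limit exact:
as $\lambda_s \to \infty$ the solution collapses onto the equal-rate
Poisson-ML clock dating (which differs by a few percent from the
tip-averaging strict clock on non-clock data; the tests distinguish the
two). The smoothing value has no published default and is an explicit
configuration; `sites` defaults to 1 and only balances data against
penalty.

**The rate grid** (`clock_grid`). Four published mitochondrial rates (COI
slow/intermediate/fast $6.5/7.5/9.5 \times 10^{-9}$; COI+tRNA+COII
$11.5 \times 10^{-9}$) crossed with both methods give eight runs whose
per-node mean is the working age estimate, with min/max reported as the
spread.

# DEC ancestral ranges and crossing counts

Ranges are subsets of ten areas (Africa, Australia, Central
America–Caribbean, East Nearctic, East Palaearctic, Northern South America,
Oriental, Southern South America, West Nearctic, West Palaearctic), capped
at two areas by default — every fixture tip coding spans at most two — so
the state space is the 10 singletons, 45 pairs and an absorbing null range.
Anagenetic evolution follows the dispersal–extinction–cladogenesis
generator: range $R$ gains area $a$ at rate
$d \sum_{b \in R} m_{ba}$ and loses an occupied area at rate $e$, where the
multiplier matrix $m$ is 1 exactly on the adjacency graph: land neighbours
(WP–EP, WP–Africa, EP–Oriental, Oriental–Australia, Africa–Oriental,
WN–EN, WN–CAm, EN–CAm, CAm–NSA, NSA–SSA) plus two transoceanic routes,
EP–WN tagged `north_pacific` (Beringia) and WP–EN tagged `north_atlantic`.
The Africa–Oriental edge can be disabled by a flag. Route availability is
constant in time: the crossings at issue happened both before and after the
Bering Strait formed, so no time-stratified closure is modelled.

Likelihood uses Felsenstein pruning with matrix exponentials
(Padé scaling-and-squaring) per branch and the classic equal-weight
cladogenetic scenarios at binary nodes (identical inheritance for
singleton ranges; allopatric splits and single-area sympatric subsets for
multi-area ranges). Polytomies are resolved internally with zero-length
branches. The root prior is uniform over adjacency-*connected* non-null
ranges: disconnected subsets such as {East Palaearctic, Northern South
America} are unreachable by stepwise dispersal, and leaving them in the
prior lets them absorb posterior mass through cladogenetic inheritance
without any dispersal event — which silently deletes the oldest crossing
from the event list. Rates $(d, e)$ are fitted by multi-start Nelder–Mead
on log rates.

Reported reconstructions are of two kinds, and the distinction matters.
Per-node *marginal* relative likelihoods (summing to one) describe
uncertainty at each node. Dispersal *events*, however, are read off the
*joint* maximum-likelihood history — a max-product (Viterbi-style) pass
over node states and scenario choices — because the per-split scenario
weights are exactly the force that localizes a crossing onto a branch;
marginals smear it toward the root. Along each branch the minimal
gain/loss path between the inherited and the node state yields the events,
each gain annotated with its source area and the route of the adjacency
edge used. Old World → New World crossings are then a filter on (source,
gained) area groups. The colonization node of an event is the child node
of its branch: the first lineage established on the far side.

# Ancestral thermal tolerances

Each taxon carries two ordered continuous characters: the mean annual
temperature of its coldest and of its warmest known locality (°C). They
evolve as correlated Brownian motion on the *phylogram* — substitution-rate
variation provides the root-to-tip path-length variation a directional
trend needs; the model warns when the tree is ultrametric, where the trend
is unidentifiable and the directional fit collapses onto the random walk.

With tip covariance $V$ (shared path lengths) transformed in the fixed
order $\kappa \to \delta \to \lambda$ (branch lengths $b \mapsto b^\kappa$
with $0^0 := 0$; all matrix entries, which are MRCA depths, raised to
$\delta$; off-diagonals multiplied by $\lambda$ with tip variances
untouched), the joint tip distribution is matrix normal:

$$\mathrm{vec}(X) \sim \mathcal{N}\!\left(\mathrm{vec}(M),\;
   \Sigma \otimes V_{\lambda\delta\kappa}\right),
  \qquad M_{ij} = \alpha_j + \beta_j \, d_i,$$

where $d_i$ is tip $i$'s transformed depth, $\alpha$ the root state,
$\beta$ the directional trend (zero under model A, free under model B) and
$\Sigma$ the $2 \times 2$ evolutionary rate matrix whose off-diagonal is
the cold/warm covariation. The density is evaluated through the
matrix-normal identity (no $2n \times 2n$ matrix is formed), and the tests
check it against a dense multivariate-normal oracle.

**Model comparison.** For fixed $\lambda$ the GLS estimates of
$(\alpha, \beta)$ and $\Sigma$ are closed-form, so the ML fit profiles a
single parameter; model B vs A is a likelihood-ratio test with two degrees
of freedom (one per trend), and a stepping-stone estimate of the log Bayes
factor from tempered MCMC chains is available as a cross-check. "Best"
means LRT $p < 0.05$ by default.

**MCMC** (`fit_mcmc`). Random-scan Metropolis–Hastings over $\alpha$,
$\beta$, $(\log \sigma_1, \log \sigma_2, \rho)$ and $\lambda$, with flat
priors on bounded supports: $\lambda \sim U[0,1]$, log-uniform rate
variances across twelve orders of magnitude around the data scale, uniform
correlation on $(-1, 1)$, and wide normal $\alpha, \beta$. $\delta$ and
$\kappa$ are fixed at 1 by default — freeing them is reported not to change
the fit materially, and flags exist to estimate them. Chains start at the
profile ML fit; only $\lambda$ (or $\delta/\kappa$) proposals trigger a new
Cholesky factor, so the desk preset (200,000 iterations, burn-in 5,000,
thinning 100) runs in seconds on 73 tips. The "paper" preset (5,000,000
iterations) reproduces the published run length. Identical seeds give
identical sample streams.

**Ancestral states** (`ancestral_states`). For each retained draw the node
value is sampled from its conditional normal given the tips under that
draw's parameters: node–tip covariances are the shared path lengths scaled
by the draw's $\lambda$, node variances are left unscaled, mirroring the
tip-level convention. Summaries are posterior means and 2.5/97.5
percentiles; a posterior mean cold limit above the warm limit is flagged,
never silently reordered.

# The Beringian paleocurve

A benthic $\delta^{18}$O series (higher = colder) is smoothed with a
50-point running mean. The window is counted in samples; even windows use
the symmetric centered moving average (half weight on the two outermost of
$w + 1$ samples) so the smoother does not shift a trend by half a sample,
and edges fall back to the largest plain symmetric window that fits. One
numerical consequence is stated honestly: because edge windows renormalize
their weights, "smoothing never increases the sample variance" holds
strictly on the interior but only up to a sub-percent boundary term on the
full series, and the tests encode exactly that.

Calibration maps smoothed $\delta^{18}$O to Beringian mean annual
temperature through three anchors — $-9$ °C today, 4 °C at 9 Ma, 11 °C at
14 Ma — as the piecewise-linear interpolant *in* $\delta^{18}$O *space*
through the (smoothed value at anchor age, anchor temperature) pairs,
extended linearly beyond the outermost anchors. Anchor-exactness was chosen
over a least-squares line (available behind `method = "linear_fit"`)
because the curve is described as calibrated *to* those temperatures, and
exact anchors give sharp testable points; anchor ages are inserted into the
output grid so that age interpolation honours them to machine precision.
Evaluation outside the series span is an error, never an extrapolation.

# Gateway tests

`tolerance_trend_test` asks whether younger colonization events have
colder-adapted ancestors: the Pearson (optionally Spearman) correlation
between event age and the chosen character, with an exhaustive one-sided
permutation null over all $n!$ orderings ($n \le 7$; with the five
colonization events a perfect ordering gives $p = 1/120 \approx 0.0083$,
which is how a significance below 0.01 is attainable at $n = 5$ at all). A
$t$-test and a posterior-sign method on the trend parameter are provided as
alternatives; the original analysis does not state which procedure produced
its trend $p$-value, so none of the three is claimed to be it.
`beringia_match` evaluates the curve at each event age and reports whether
it falls inside the ancestor's tolerance interval, with a distance-to-interval
column so near-misses stay visible (default margin 0 °C).
`fitch_mp` reconstructs the unordered hostplant-family character by
unit-cost parsimony; the returned per-node sets are full MPR sets (states
occurring in at least one globally most-parsimonious assignment), computed
by dynamic programming and verified against exhaustive enumeration.

# Simulators and the fixture

Every simulator is a pure function of parameters and seed. Trees are
birth–death chronograms conditioned on $n$ tips, with lognormal per-branch
rate noise deriving the phylogram. Traits are drawn jointly for tips and
internal nodes from the exact transformed covariance, so node-level truth
is available for coverage checks. DEC histories are Gillespie simulations
recording every event. The $\delta^{18}$O generator produces a linear
cooling trend (2.0 ‰ at 14 Ma to 4.2 ‰ at present, the scale of the real
benthic record) plus white noise, 300 samples by default.

`fixture_polyommatus` is the hand-encoded 19-tip genus backbone: Chilades
sister to the rest; the Neotropical clade (Echinargus, Hemiargus, Cyclargus
plus South American representatives) sister to Freyeria + the Holarctic
taxa; Icaricia–Plebulina (with *saepiolus*), Lycaeides, Agriades and
Vacciniina each with an Old World sister; the three Holarctic species that
span the strait appear as separate OW/NW tips with disjoint ranges. The
five colonization nodes carry the published mean ages (10.7, 9.3, 2.4, 1.1,
1.0 Ma); all other node ages are interpolated scaffolding, and the
companion phylogram applies fixed-seed lognormal rate noise at
0.0075 subs/site/Ma. The tolerance table is synthetic (the WorldClim-derived
per-taxon table is not published in machine-readable form): hand-set
plausible values, warm tropical taxa to cold arctic-alpine ones.

# What the tests show, and what they cannot

The suite verifies the machinery against independent oracles (exhaustive
DEC enumeration, dense multivariate normals, unit-cost Sankoff, GLS closed
forms, analytic limits) and reproduces, on the fixture and simulations: the
five north-Pacific crossings, the hostplant families of the five ancestors,
the three calibration anchors, the $1/120$ permutation bound, and recovery
of a generating $\lambda$ of 0.925 within $\pm 0.1$ (mean over ten 73-tip
replicates).

They do not re-derive the published colonization ages or the published
$\lambda$ from empirical data: that requires the GenBank sequence set
(GQ128446–GQ129111), externally inferred trees (tree search is out of
scope here) and the unpublished supplementary climate tables. To reproduce
those numbers one would align the sequences, infer the ML phylogram and
Bayesian chronogram, extract per-taxon WorldClim temperatures at range
extremes, and feed those inputs through `run_pipeline` — the interfaces
accept exactly those artifacts.

# Problem sizes used by tests and scripts

Simulation-backed checks run at deliberately chosen desk scales: ten 73-tip
MCMC replicates at the 200k-iteration desk preset for $\lambda$ recovery,
twenty 30-tip forward DEC histories for event recovery, fifty 20-tip
replicates per model for the LRT choice rates, twenty 15-tip replicates for
ancestral-state coverage, and 100–200 small trees for round-trip and MRCA
properties. These sizes are the package's own choices balancing statistical
resolution against runtime; raising them changes no interface.
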