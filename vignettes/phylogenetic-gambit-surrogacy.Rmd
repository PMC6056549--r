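---
title: "Measuring the surrogacy of phylogenetic diversity for functional diversity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the surrogacy of phylogenetic diversity for functional diversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

Conservation planners often cannot measure the traits that matter for
ecosystem function, so a popular wager — the *phylogenetic gambit* —
holds that protecting phylogenetic diversity (PD) will indirectly
protect functional diversity (FD), because traits are inherited along
the phylogeny. `phylogambit` quantifies exactly how much FD a
PD-maximizing prioritization captures, relative to two benchmarks:
random selection (the floor) and direct FD maximization (the
ceiling). This vignette explains the models and algorithms, the
parameters that matter, the design choices where the procedure is
genuinely open, and the limits of what the package's synthetic
validation can show.

## Trait space

Species traits of mixed type (numeric, categorical, ordinal) are
combined with the Gower dissimilarity, in which each trait contributes
on a [0, 1] scale: numeric traits as absolute differences divided by
the pool range, unordered categories as 0/1 mismatches, ordered
categories rank-scaled to [0, 1] and treated numerically. Missing
values are handled by pairwise deletion; only a species pair sharing
no trait at all is an error. The computation is delegated to
`cluster::daisy()`; a body-mass-style preprocessing helper
(`preprocess_traits()`) applies natural-log transforms and pool-range
rescaling to named columns first.

The Gower matrix is embedded by classical principal coordinates
(`pcoa_embed()`): eigendecomposition of the double-centered squared
distances, axes scaled by the square roots of their eigenvalues.
Mixed-trait Gower matrices are generally non-Euclidean, so some
eigenvalues are negative; by default they are simply discarded and
variance fractions are computed over the positive spectrum only, with
Cailliez and Lingoes corrections available as a configuration switch
(`correction =`). The number of retained axes is the smallest that
explains 70% of the (positive) variance; 0.70 is the package default
and `variance_threshold = 0.80` is a one-line robustness check, since
conclusions should not hinge on the retention rule.

Phylogenetic signal of each retained axis is summarized by Blomberg's
K (`blomberg_k()`), computed analytically: the ratio of the observed
mean squared error of the trait about its phylogenetic
generalized-least-squares mean to the error expected under Brownian
motion on the tree, normalized by the analytic Brownian expectation
derived from the tree covariance matrix. K is scale- and
location-invariant and has expectation 1 under Brownian motion. We
compute the expectation from the covariance matrix rather than by
simulation because it is exact and cheap for pools up to a few
thousand tips.

## The three prioritization strategies

**Random.** For each richness decile (10%, ..., 100% of the pool,
`k = round(fraction * n)` with a floor of 2 — see *Numerical choices*),
`n_random` uniform subsets are drawn and their functional richness
averaged. Per-replicate values are retained for the reliability
statistic.

**maxPD.** Faith's PD of a set is the summed branch length of the
minimal subtree connecting the set *and the root*; we use the rooted
convention throughout, so a singleton's PD is its root-to-tip path.
The greedy selector (`greedy_max_pd()`) adds, at each step, the
species with the largest PD increment; for rooted PD this greedy
procedure attains the true optimum for every k, which the test suite
verifies against exhaustive enumeration. Increment ties (within a
relative 1e-9 of total tree length — calibrated trees carry
floating-point branch lengths) are broken uniformly at random;
`sets_per_tree` independent tie-break streams per tree yield multiple
co-optimal sets, and when fewer distinct optima exist duplicates are
kept so averages remain uniformly weighted. Selections are nested in
k, so a single greedy ordering provides all deciles. Averaging FD over
trees x tie-sets propagates both phylogenetic uncertainty and tie
ambiguity into the surrogacy estimate.

**maxFD.** Functional richness (FRic) is the convex-hull volume of the
selected species in the retained trait space — the range in one
dimension — computed by a compiled incremental (beneath-beyond) hull
algorithm; sets with at most d points, or affinely degenerate sets,
have zero d-volume by contract. Because maximizing hull volume
directly is combinatorial, the benchmark uses a penalized greedy
heuristic (`greedy_max_fd()`): seed with the farthest pair, then
repeatedly add the candidate maximizing
`||x - centroid(selected)|| + K * exp(L * minD)`,
where `minD` is the candidate's distance to its nearest selected
neighbour. The exponential term disfavours candidates that are far
from the centroid but redundant with an already-selected species. The
penalty strength is not chosen by hand: `tune_and_select()` draws
`n_param_draws` `(K, L)` pairs from a normal(1, 0.5) truncated to the
positive half-line and keeps the selection with the largest FRic. We
truncate at zero because non-positive K or L would make the penalty
non-positive or non-monotone, defeating its purpose; the tuning is
re-run independently per pool and per decile, which dominates any
single global pair.

## Surrogacy and reliability

With the three accumulation curves on a common decile grid, the
surrogacy index is the area ratio

S = 100 * A / (A + B),

A being the trapezoidal area between the maxPD and random curves and
A + B the area between the maxFD and random curves. The area-ratio
form is the primary definition because at the final decile all three
strategies select the whole pool and a pointwise ratio degenerates to
0/0 there; the pointwise form (mean per-decile ratio, final decile
excluded) is available via `surrogacy_form = "pointwise"` for
sensitivity analysis. Deciles where the maxFD hull is degenerate
(volume 0, possible when `k <= retained_d`) are excluded from both
integrals. When even the denominator area is below `1e-12 x` pool FRic
— random selection already saturates FD, which happens in
functionally redundant, species-rich pools — the index is undefined
and reported as `NA` rather than an unstable quotient.

The reliability fraction asks a sharper question than the mean: across
all pairings of one random-set FD sample with one maxPD-set FD sample
(per decile, then averaged over deciles), how often did the random set
hold *more* FD? It is computed by sort-and-count in O(n log n),
contract-identical to the naive double loop (property-tested). The
final decile, a structural tie, is excluded by default
(`include_last = FALSE`) as it only dilutes the statistic with zeros.

## The synthetic-data generator

The generator supplies every input the analysis needs, with the
statistical structure the method assumes:

* **Trees** — pure-birth (default) or birth-death trees conditioned on
  tip count via `ape::rphylo`, hence ultrametric ("calibrated");
  extinction is off by default so the gamma statistic is centred on
  its standard-normal null, which the tests exploit.
* **Tree sets** — pseudo-posterior samples made by multiplying each
  branch by independent lognormal(0, sd) noise and restoring
  ultrametricity by extending terminal branches to the maximum
  post-jitter depth. This preserves topology and internal-edge noise;
  the default `branch_jitter_sd = 0.1` keeps depth distortions in the
  ~10% range typical of posterior credible sets.
* **Traits** — each continuous trait is
  `sqrt(s) * z_BM + sqrt(1 - s) * z_WN` with `z_BM` a unit-variance
  Brownian realization on the tree and `z_WN` white noise; the single
  knob `s = signal_mix` tunes Blomberg's K continuously between ~0 and
  ~1. Categorical traits bin an independent latent trait of the same
  construction into equal-frequency levels — a latent-threshold scheme
  chosen over Mk simulation so one signal knob governs every trait,
  and equal frequencies avoid degenerate single-level factors that
  break Gower. The default `signal_mix = 0.8` reflects the strong but
  imperfect signal typical of ecomorphological traits; the default
  trait table (2 continuous + 2 three-level categorical) mirrors a
  small Eltonian trait set.
* **Pools** — seeded subsets of the species list with controllable
  sizes and overlap, standing in for assemblages or clades.

Everything is a pure function of (configuration, seed); stage seeds
are derived from the master seed by hashing labels such as
`"pool03/random"`, so results do not depend on iteration order.

What the generator does **not** emulate: spatial autocorrelation of
assemblages, diversification-rate shifts, trait-dependent speciation,
composition-type traits (e.g. diet percentages), and realistic
phylogenetic error beyond branch-length jitter (no topological
uncertainty). Passing the recovery tests therefore shows the pipeline
measures what it claims under its own assumptions — not that any
empirical system satisfies those assumptions.

## Numerical choices

* `k = round(fraction * n)` with a floor of 2: hull volumes and the
  pair-seeded selector need at least two species. (The floor matters
  only for pools at the minimum size; the 10% decile of a 10-species
  pool selects 2, not 1.)
* Minimum pool size 10 (configurable): below this the decile grid
  collapses and hulls are degenerate for typical retained
  dimensionalities; undersized pools are skipped and logged, never
  fatal.
* PD increment ties at relative 1e-9; PCoA eigenvalues are "positive"
  above `1e-8 x` the leading eigenvalue; hull degeneracy at
  `1e-9 x` coordinate spread; curve-grid equality at 1e-12.
* Aldous' beta is estimated by bounded scalar maximum likelihood on
  [-1.999, 10] (`optimize`, tolerance 1e-9) with a grid-search
  fallback; the split-size likelihood is evaluated in log space with
  per-clade-size caching.
* Trapezoidal quadrature on the decile grid for both surrogacy areas;
  the grid is coarse and fixed, so the rule is part of the definition.

## Validation design

The test suite layers independent oracles under every stage: hand
enumeration for Faith's PD; exhaustive subset enumeration for both
greedy selectors; the shoelace formula (and, once, an external
computational-geometry library) for hull volumes; direct formula
evaluation for Gower, gamma and the PCoA spectrum; Monte-Carlo nulls
for gamma, beta and Blomberg's K; and an analysis-level recovery
experiment — with full Brownian signal the mean surrogacy across 30
synthetic pools is positive, and with no signal it is statistically
indistinguishable from zero, the behaviour the gambit predicts.
Replicate counts in the recovery experiment are scaled to 200 random
sets, 10 trees x 3 tie-sets and 100 parameter draws per decile, sizes
at which the Monte-Carlo error of the pool-mean surrogacy is small
relative to the recovered effect.

## Known limitations

* The penalized greedy maxFD selector optimizes *dispersion*, not
  volume. On average it closely approaches the brute-force optimum
  (mean ratio ~0.98 on random 2-d pools in our oracle tests), but it
  is not uniformly adequate: for k near the space dimensionality it
  can return a thin, near-degenerate simplex whose volume is a small
  fraction of the optimum, and no (K, L) pair rescues it because the
  seeded farthest pair and dominance in both score components pin the
  selection. Deciles in that regime carry little hull volume by
  construction; at realistic pool sizes (k well above d) the
  approximation is tight. Users comparing strategies at very small k
  in high-dimensional spaces should treat the maxFD ceiling as a lower
  bound on the true optimum — which makes reported surrogacy values
  conservative in the other direction (S can exceed 100% in principle).
* Rooted PD is the only PD flavour wired into the curves (the
  definition used throughout); unrooted PD of a fixed set is available
  via `faith_pd` on a re-rooted tree but not as a selection target.
* FRic ignores abundance and interior structure; it is deliberately
  the richness facet of FD, set-monotonic under species addition.
* Beta imbalance requires a fully bifurcating topology; pools pruned
  to polytomies report `NA` for that covariate.
* The surrogacy index inherits Monte-Carlo noise from all three
  curves; at the default replicate counts this noise is small, but for
  pools where random selection nearly saturates FD the index is a
  ratio of two small areas and is reported `NA` below the guard
  threshold rather than amplified.
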