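---
title: "Range-constrained co-occurrence simulation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Range-constrained co-occurrence simulation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(racocos)
```

## The inference problem

Fewer-than-expected co-occurrences between two taxa are the classical
(indirect) evidence of competitive exclusion, and hence of niche overlap.
But "expected" is treacherous for dispersal-limited taxa: two species
whose ranges never meet co-occur zero times for purely geographic
reasons, and records harvested from museum collections add a second
distortion — some sites were searched exhaustively, others cursorily.
`racocos` builds the null expectation *conditional on geography* and
offers explicit corrections for effort bias, so that what remains outside
the null envelope can be attributed to taxon interactions.

## The model

### Spatial weights

Every pair of sites gets a weight from a logistic distance-decay kernel,

$$W_{ij} = \frac{1}{1 + e^{\,k(\ln(d_{ij}+\delta) - \ln d_0)}}
        = \frac{1}{1 + \left(\frac{d_{ij}+\delta}{d_0}\right)^{k}},$$

with $W_{ii} = 1$ by definition. Parameters, units and defaults:

* $d_0$ (km) — the half-weight distance: $W = 0.5$ exactly at
  $d = d_0 - \delta$. Biogeographically, the transition between relevant
  and irrelevant distances for jump dispersal of rock-dwelling snails
  lies between 10 and 100 km, so the default grid uses 30 and 50 km.
* $k$ (dimensionless, > 0) — steepness of the decay. The standard grid
  crosses $(k, d_0) \in \{(5, 30), (3, 30), (10, 50)\}$: under $(5, 30)$
  the weight falls from $\approx 1$ at 10 km through 0.5 at 30 km to 0.07
  at 50 km and 0.01 at 75 km; $(3, 30)$ is smoother (0.77 at 20 km, 0.06
  at 75 km); $(10, 50)$ keeps near-full weight to 30 km (> 0.99) and
  halves at 50 km. Running several settings is cheap insurance: results
  that depend on the kernel choice should not be over-interpreted.
* $\delta$ (km, default 0.1) — added to all distances so the log-distance
  form is defined at $d = 0$. It is configurable to support sensitivity
  analyses; at the default smoothing settings its effect is negligible
  (the self-weight is pinned to 1 anyway).

The logarithm is natural. Note that the base is not a free choice
independent of $k$: using $\log_{10}$ is equivalent to multiplying $k$ by
$\ln 10 \approx 2.3$, so all $k$ values quoted here and in the defaults
assume $\ln$. The power form on the right is used in the implementation
(one `exp`/`log` round-trip fewer); the two agree to machine precision
and a test holds them to $10^{-12}$ relative error.

Distances are great-circle (haversine, mean Earth radius 6371.0088 km)
for lon/lat input, Euclidean for planar x/y in km (synthetic data), or a
user-supplied matrix.

### Occurrence probability

The range of taxon $t$ is not a polygon but a surface:
$$OP_{it} = \frac{\sum_j W_{ij} Y_{jt}}{\sum_j W_{ij}},$$
the spatially weighted fraction of presence sites. $OP \in [0, 1]$; a
taxon present everywhere has $OP \equiv 1$, one present nowhere
$OP \equiv 0$. Because $W_{ii} = 1 > 0$, the denominator never vanishes.
OP reflects record density within the range, interleaving of two taxa
inside a shared region, and regional allopatry — which binary range maps
(e.g. convex hulls) cannot.

### Selection weights and the three corrections

Simulated matrices must hold the observed total presence count
$N = \sum Y$ fixed. The per-cell selection weights are:

* **uncorrected** — $OP$ rescaled once so its total is $N$;
* **hard** — each row $i$ of $OP$ multiplied by $n'_i$, a uniformly
  permuted copy of the observed per-site richness vector $n$ (row sums of
  $Y$), then rescaled to $N$. Sites drawing $n'_i = 0$ are excluded from
  that round — exactly as many per round as there are empty sites in $Y$;
* **soft** — as hard but with $n' + 1$, so no site is ever excluded; it
  sits between the other two in how closely it matches the observed
  richness distribution.

The permutation is redrawn before *every* round; this is what lets
uneven sampling effort be simulated under the assumption of equal habitat
suitability, rather than freezing the observed effort onto specific
sites. The raw OP matrix itself is computed once and held fixed across
rounds — only the richness permutation changes — since OP is a property
of the observed ranges, not of any simulated round. The rescaling is
applied once at matrix level (no per-row renormalization), so elements
stay proportional to $n'_i \cdot OP_{it}$.

### Drawing a null matrix

A simulated matrix sets exactly $N$ distinct cells to 1, drawn without
replacement with per-draw probability proportional to the remaining
positive weights: doubling a cell's weight doubles its chance in each
selection round. The implementation uses exponential-key order statistics
— select the $N$ cells with smallest $\mathrm{Exp}(1)/w$ keys — which has
exactly that sequential per-draw law but is vectorized; any algorithm
with the same law is conformant, and the test suite checks the
distribution against base R's sequential `sample(prob =, replace =
FALSE)` as an independent oracle. Zero-weight cells are excluded from the
sampling universe outright, so they can never be selected. Sampling is
done jointly over the whole site-by-taxon matrix (not per site), because
the corrections constrain the full-matrix total.

### Envelopes, classification, and the rescaled statistic

Each of `n_rounds` (default 1000) rounds yields pairwise co-occurrence
counts (sites where both taxa are present; a site with $n$ presences
contributes $(n^2 - n)/2$ pairs). Per pair, the minimum, mean and maximum
over rounds form the envelope; the observed count $m$ is classified
with *inclusive* bounds — `below` ($m < \mu_{min}$), `above`
($m > \mu_{max}$), otherwise `within_zero`/`within_nonzero` by whether
$m = 0$. Ties at the envelope edge therefore count as within, the
conservative reading of a range test. For visual comparison, $m$ is
rescaled piecewise-linearly so that $\mu_{min} \mapsto -1$,
$\bar\mu \mapsto 0$, $\mu_{max} \mapsto +1$:

$$m' = \frac{m - \bar\mu}{\bar\mu - \mu_{min}} \;(m \le \bar\mu), \qquad
  m' = \frac{m - \bar\mu}{\mu_{max} - \bar\mu} \;(m > \bar\mu).$$

When the relevant denominator is zero — routine for rare or allopatric
pairs, whose simulated ranges usually include zero — $m'$ is reported as
`NA`, never as a silent 0; the classification is still made. This
degeneracy is precisely why counts are also cumulated by relatedness
group: observed counts are summed within each category, simulated counts
are summed within the category *after each round*, and the group envelope
is the min/mean/max of those per-round sums. Summing per-pair minima or
maxima instead would be wrong (per-round extremes of different pairs need
not coincide); a regression test pins this down.

### Relatedness categories

Each taxon carries an ordered rank path (class, subclass, family,
subfamily, genus, main clade, subclade, species; deeper ranks may be
unresolved). A pair's category is determined by the first rank at which
both members are resolved and differ: divergence at the subclass maps to
category I (related at the class level) down to divergence at the species
rank, category VII (congeneric morphospecies). The rank-to-category map
is configuration, not code, so other study systems can restratify.
Column pooling (merging taxa by logical OR at a chosen rank) lets one raw
matrix drive analyses at several taxonomic resolutions; the hierarchy is
pooled alongside so stratification survives pooling.

## Random numbers and reproducibility

A master seed drives everything. Ensembles pre-draw one child seed per
round (all < 2^31) and reseed at the start of each round, so results are
independent of evaluation order and bitwise reproducible. The full
resolved configuration, including the seed, is written next to every
artifact bundle.

## The synthetic generator

`synthetic_scenario()` emulates the statistical structure the method
assumes, not any particular fauna: sites clustered by a Thomas-type
parent–offspring process (limestone outcrops and collector itineraries
are both clustered); per-taxon Gaussian range kernels in distance
(monotone and consistent with the distance-decay rationale; other kernels
could be substituted) with bandwidths of 30–120 km on a 500 × 500 km
extent, giving partial allopatry; lognormal per-site effort multipliers
(mean 1, $\sigma = 1$) which produce the right-skewed, platykurtic
taxa-per-site distributions typical of opportunistic sampling; and
optional imposed exclusion pairs, where one member of a co-occurring pair
is deleted at random — the known-truth signal for power checks. Defaults
(1649 sites, 40 taxa) match the scale of a large museum compilation.

What it does *not* emulate: mechanistic colonization–extinction dynamics,
phylogenetically correlated range evolution, habitat heterogeneity, or
taxon-specific detectability interacting with effort. Passing tests on
synthetic data therefore demonstrate that the machinery recovers imposed
structure under the model's own assumptions — not that those assumptions
hold for any real dataset.

## Numerical and design choices

* Diagonal of $W$ pinned to exactly 1, not the $\approx 1$ the offset
  formula yields at $d = 0$.
* Selection-weight totals are held to $N$ within floating tolerance
  ($10^{-9} N$ in tests); simulated matrices hold $N$ exactly by
  construction.
* Taxa with zero presences stay in the analysis as all-zero columns;
  their pairs are degenerate (envelope [0, 0], class `within_zero`).
* `pool_columns` leaves columns unresolved at the pooling rank unchanged
  rather than erroring: mixed-resolution matrices (a focal genus split
  finely, outgroups binned coarsely) are the normal case.
* Per-taxon co-occurrence load is defined as the mean over a taxon's
  presence sites of (site richness − 1); the alternative bookkeeping —
  number of distinct partner taxa — is exposed alongside in the same
  table.
* Skewness and excess kurtosis are the bias-uncorrected sample moments
  (e1071 type 1), recorded in the diagnostics output.

## Validation strategy and problem sizes

The test suite checks every closed-form anchor of the kernel and the
rescaled statistic exactly; verifies OP, co-occurrence counts and
corrected weights against brute-force enumeration on tiny fixtures;
checks the sampler's per-draw law against exact multinomial frequencies
and against base R's sequential sampler; and establishes four ensemble
properties on synthetic data — conservation of $N$ in every round;
ordering of mean total simulated co-occurrences (hard ≥ soft ≥
uncorrected) on right-skewed data at 200 sites × 25 taxa × 200 rounds;
null calibration (a matrix drawn from the uncorrected null falls outside
its own 1000-round envelope at ≈ 2/1001 per pair, by exchangeability) at
40 sites × 33 taxa; and power (an imposed exclusion between sympatric
taxa classified `below` under the hard correction in ≥ 90% of 50 seeds)
at 300 sites × 500 rounds. These sizes were chosen as the smallest at
which each property is statistically sharp.

## Known limitations

* One global $(k, d_0)$ per model run: taxon-specific dispersal
  parameterization is plausible biology but out of scope.
* The hard correction corrects for the *average* bias; taxa sampled much
  better or worse than average can be over- or under-corrected, which is
  why results should be read across all nine model combinations.
* Envelope tests use the simulated range, not tail probabilities; with
  1000 rounds the implied two-sided level is about 2/1001, and
  `n_rounds` is the only dial.
* Group cumulation can be dominated by widespread, record-rich pairs;
  interpret group-level departures together with the pairwise table.
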