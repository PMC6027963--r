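# racocos

Range-constrained co-occurrence simulation for binary presence–absence
data.

## The problem

Classical co-occurrence null models (checkerboard swaps, fixed-margin
randomizations) assume every taxon could occur at every site. For
dispersal-limited, partially allopatric taxa — rock-dwelling land snails
are the motivating case — that assumption is wrong twice over: two taxa
may never co-occur simply because their ranges do not meet, and
opportunistically collected (museum) records carry strong, uneven
sampling-effort bias. Both effects masquerade as ecological signal.

`racocos` addresses this with a three-part framework:

1. **Probabilistic ranges.** Each pair of sites *i, j* gets a logistic
   distance-decay spatial weight

   W_ij = 1 / (1 + e^{k (ln(d_ij + 0.1) − ln d_0)}) = 1 / (1 + ((d_ij + 0.1)/d_0)^k),

   with W_ii = 1, where d_ij is the inter-site distance in km, d_0 the
   half-weight distance and k the steepness (0.1 km is added so the
   logarithm is defined at zero distance). The occurrence probability of
   taxon *t* at site *i* is the weighted presence fraction

   OP_it = Σ_j W_ij Y_jt / Σ_j W_ij,

   a smoothed utilization surface that is high only where the taxon has
   nearby records.

2. **Range-constrained null simulation.** The OP matrix is rescaled to
   selection weights summing to the observed number of presences N, and
   simulated presence–absence matrices Ψ with exactly N presences are
   drawn by unequal-probability selection without replacement (doubling a
   cell's weight doubles its per-draw chance). Three weight schemes are
   provided: *uncorrected* (OP only), *hard* (each row multiplied by a
   freshly permuted copy of the observed per-site richness vector — the
   simulated taxa-per-site distribution then tracks the observed, biased
   one), and *soft* (the permuted vector plus one, so no site is ever
   excluded).

3. **Envelope tests.** Over (by default) 1000 rounds, each taxon pair's
   simulated co-occurrence counts yield a min–mean–max envelope. Observed
   counts m are classified below / within (zero) / within (non-zero) /
   above the envelope, and rescaled to m′ ∈ {−1, 0, +1} at the envelope
   minimum/mean/maximum. Because rare or allopatric pairs often have
   envelopes that include zero, counts can also be cumulated by
   taxonomic/phylogenetic relatedness category (I–VII, from class-level to
   congeneric morphospecies pairs), with group envelopes computed from
   per-round group sums.

The package also ships a synthetic-data generator (clustered sites,
Gaussian range kernels, lognormal sampling-effort multipliers, imposed
pairwise exclusion), sampling-bias diagnostics (taxa-per-site
distributions, per-taxon co-occurrence load), flat-file I/O and a CLI.

## Worked example

Simulate a biased, clustered study system in which taxa `t001` and `t002`
are broadly sympatric but never co-occur (imposed competitive exclusion),
then test all pairs against the null:

```r
library(racocos)

sc <- synthetic_scenario(n_sites = 200, n_taxa = 12,
                         bandwidth_km = c(150, 350), prevalence = c(0.5, 0.9),
                         effort_sigma = 1, exclusion_pairs = cbind(1, 2),
                         seed = 42)
sites <- generate_sites(sc)
Y <- generate_presence(sc, sites)$Y

run <- racocos_run(sites, Y, taxonomy = generate_taxonomy(sc),
                   k_d0 = list(c(5, 30)), n_rounds = 500, seed = 7,
                   distance_mode = "euclidean")
print(run)
#> Range-constrained co-occurrence analysis
#>   sites: 200  taxa: 12  presences: 723
#>   models: 3  rounds each: 500
#>   k5_d030_uncorrected      below/within0/within+/above: 1/0/50/15
#>   k5_d030_soft             below/within0/within+/above: 1/0/63/2
#>   k5_d030_hard             below/within0/within+/above: 1/0/65/0
```

The four numbers per model count pairs below / within (observed zero) /
within (observed non-zero) / above their simulated envelopes. The
uncorrected model reports 15 pairs *above* expectation — an artifact of
the right-skewed sampling effort (the data's taxa-per-site skewness is
0.65); the hard correction absorbs all of them. The one robust `below`
pair in every model is the imposed exclusion:

```r
subset(run$models[["k5_d030_hard"]]$pairs, taxon_a == "t001" & taxon_b == "t002")
#>   taxon_a taxon_b m mu_min mu_mean mu_max  m_prime class
#> 1    t001    t002 0      6  14.574     24 -1.69979 below
```

Zero observed co-occurrences against a simulated envelope of 6–24 is
fewer than expected under the shared-range null (m′ = −1.70, i.e. beyond
the envelope minimum) — the signature of niche overlap, not allopatry.
Group-cumulated counts (`run$models[[...]]$groups`) report the same test
per relatedness category.

Command-line equivalents: `inst/cli/racocos.R {run|synth|diagnose}`.

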