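---
title: "Methods: bee community diversity and bee-plant co-occurrence networks for in-field prairie strips"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity and co-occurrence networks for prairie strips}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prairienet)
```

## The study system and the data model

`prairienet` analyses paired-field bee surveys of the kind used to evaluate
in-field prairie strips: bands of reconstructed native perennial prairie
vegetation occupying roughly 10--12% of a row-crop field ("strip"
treatment), contrasted with 100%-crop "control" fields at the same site.
The canonical design is four paired comparison sites, two treatments, two
years, and four monthly sampling rounds (May--August), giving 64 sampling
events.  Each event yields bee abundance counts per taxon along a 60-m
transect (all trap types pooled) and, in strip fields, the proportional
cover of each blooming forb species (pre-averaged over ten 1-m^2 quadrats).

All tables are long (tidy) format -- one row per
(site, treatment, year, month, taxon) -- because the site-by-month pairing
unit is exactly what the correlation stage needs; wide matrices are derived
views (`community_matrix()`).  Months are categorical with the fixed order
May < Jun < Jul < Aug; nothing finer than the four monthly rounds is
modelled.  Missing (site, month, taxon) combinations are absences (zeros),
not missing data: trap and quadrat surveys record absences implicitly.
Validation is total -- a non-integer bee count, a plant cover outside
[0, 1], a duplicate key, or a taxon absent from the registry is a located
error, never silently repaired.

One bee taxon may be flagged *pooled*: a taxonomically intractable
assemblage (the *Lasioglossum* subgenus *Dialictus*) treated as a single
taxon.  Because this assemblage is typically both ubiquitous and dominant,
several analyses are run with and without it (the "8 common" versus
"9 common" readings below).

## The synthetic generator

No field data ship with the package; every stage is exercised against a
generator with known ground truth (`synthetic_truth()`,
`generate_dataset()`).  The generator emulates:

* **Community scale.** 89 bee taxa over five families (Halictidae, Apidae,
  Andrenidae, Colletidae, Megachilidae) including one pooled Halictidae
  taxon, and 55 forb taxa (27 native prairie, 28 exotic/weedy) over
  seventeen families.
* **Abundance structure.** Per-species log-baselines are drawn
  `Normal(-3.5, 2.6)`; the pooled taxon is the sum of six latent species
  with baseline `log-mean 1.0`.  These values were fixed once so that a
  default draw yields a few thousand individuals, a pooled taxon holding
  roughly a third of all individuals, and a realized set of roughly ten
  species above the 1% commonness boundary -- the steep, pooled-dominated
  structure such surveys show.  `commonness_target` (default 0.1) documents
  the intended fraction; the realized count is stochastic.
* **Treatment and phenology.** The strip treatment adds `log(1.6)` to every
  bee's log-mean (a 1.6-fold abundance increase); month effects default to
  a July peak (`-0.3, 0, 0.4, 0.1`).
* **Plant cover.** Per strip event, a Dirichlet-like draw: per-species
  gamma propensities (lognormal heterogeneity across species) normalized
  and scaled to a total blooming cover of 0.5.
* **Couplings.** A bee-by-plant matrix of effect sizes `beta` (log-mean
  increase per unit proportional cover) links bee counts to plant cover in
  strip fields; `coupling_month` restricts a coupling to one month.
  Counts are Poisson on the log link -- deliberately so, because the
  Pearson screening step must be shown to work on realistic small-count
  discreteness, not Gaussian idealizations.
* **Visitation.** A bee-by-plant matrix of observed flower visits,
  Poisson with mean `visit_rate * max(beta, 0) * mean cover`, i.e.
  consistent with the planted couplings.
* **Landscape.** Per-field land-cover profiles with two crop and several
  non-crop categories; the realized non-crop proportion is uniform over
  a configurable range, default 8--69%.

Everything is bit-reproducible given the truth's seed.  What the generator
does **not** emulate: spatial foraging and between-field movement,
within-season population dynamics, trap-type differences (collapsed by the
data model), overdispersion beyond the Poisson-lognormal mixture, and
observation error in cover estimates.  Passing recovery tests therefore
show the pipeline is correct and calibrated for this mechanism, not that
real surveys satisfy the mechanism.

## Diversity

`hill_number()` implements the order-0, 1, 2 effective species numbers
(richness, exponential Shannon, inverse Simpson); sensitivity to rare
species decreases with the order q, which is why the three are reported
together when common and uncommon species may respond differently.

`rarefaction_curve()` produces sample-size-based interpolation and
extrapolation:

* q = 0 interpolation is the exact hypergeometric closed form
  (`rarefy_richness()`), `S_obs - sum_i C(n - X_i, m) / C(n, m)`.
* q = 1, 2 interpolation is a seeded Monte-Carlo subsampling expectation
  (default 100 subsamples per grid point) rather than the analytic
  estimators.  The Monte-Carlo route is simpler, testable against an exact
  enumeration oracle at small n, and the package's guarantees are
  property-based rather than curve-matching.
* q = 0 extrapolation augments the observed richness with a Chao1-style
  unseen-species estimate `f1^2 / (2 f2)` (with the `f1 (f1 - 1) / 2`
  fallback when no doubletons exist); q = 1, 2 are held at the plug-in
  asymptote.  Extrapolation beyond twice the observed sample size is
  refused with a warning, following standard guidance against long-range
  extrapolation.
* Confidence bounds are `estimate +/- 1.96 * SE` with the SE taken over
  bootstrap resamples of individuals (multinomial, default 100).  Raw
  percentile intervals were rejected because bootstrap richness is biased
  low, so a percentile interval can exclude the point estimate; the
  symmetric form keeps the interval anchored on the estimate, at the cost
  of ignoring bootstrap skewness.

`shannon_landscape_diversity()` is `H' = -sum(p_i log p_i)` over land-cover
category proportions (validated to sum to 1 within 1e-9;
zero-proportion categories contribute nothing), and
`noncrop_proportion()` sums the categories flagged non-crop -- the
landscape-complexity axis on which habitat-management benefit is usually
interpreted.

## Community comparison

`classify_commonness()` partitions taxa at a strict `> 1%` study-wide
relative abundance boundary (all sites, treatments, years, months pooled).
The relative-abundance denominator always includes the pooled taxon;
`mode = "exclude_pooled"` merely drops it from the candidate set, which is
what produces the 8-common versus 9-common variants.

`bray_curtis_matrix()` delegates to `vegan::vegdist`.  Two all-zero units
make the dissimilarity undefined and are refused by name.

`mrpp()` tests composition: the observed statistic is
`delta = sum_g (n_g / N) * (mean within-group distance)` -- the `n_g / N`
group weights are the common default of the procedure's reference
implementations, chosen because the method's users expect them.  The null
distribution is Monte-Carlo (default 9999 seeded permutations of the
labels, sizes fixed) with `p = (1 + #{delta_perm <= delta_obs}) /
(n_perm + 1)`, rather than the Pearson-type-III moment approximation:
exact at desk scale and testable against exhaustive enumeration
(`exhaustive = TRUE`, feasible to 10 units).  `T` standardizes
`delta_obs` against the permutation distribution and
`A = 1 - delta_obs / E(delta_perm)` is the chance-corrected agreement.
Note `A` has a small negative bias on very small unit sets (the
permutation mean sits in the denominator), visible in the null-behaviour
tests.

`multivariate_dispersion()` implements the beta-dispersion reading of
evenness: `pcoa()` (Gower double-centering, all axes retained), per-group
spatial centroids -- centroids, not medians -- and per-unit distances to
the own-group centroid with squared imaginary-axis contributions
subtracted, the standard correction because Bray-Curtis is non-Euclidean.
Negative squared distances arising from that subtraction are truncated at
zero.  Group mean distances are compared by one-way ANOVA, with an
optional label-permutation p-value.  Sampling units are events
(site-by-month-by-year); a species-profile reading (distances between
species across events) is available through
`bray_curtis_matrix(margin = "species")` but is reported descriptively
only, since the unit-level reading is the standard, testable one.

## The co-occurrence network

The core computation screens every bee-plant pair for association from
survey data alone.  For the overall network, the pairing unit is
(site, month, year) in strip fields -- up to 32 paired observations --
with both series aligned on the union of events present in either table
and absences entered as zeros (zero-inflation is deliberately not modelled:
the procedure is plain Pearson, and its behaviour on sparse series is part
of what the calibration tests measure).  Cells with fewer than three
events or a constant series are undefined: recorded, never significant.

The two-sided p-value comes from `t = r sqrt((n-2)/(1-r^2))` on n - 2
degrees of freedom, with a separate one-sided sign filter -- selection
requires `r > 0` **and** `p < alpha` (strict), because the two criteria
are conceptually independent (association strength versus direction).
Benjamini-Hochberg adjusted p-values (`bh_adjust()`, delegating to
`stats::p.adjust`) are always computed alongside; the unadjusted network
is the default working network, with `use_adjusted = TRUE` as the
conservative variant.  The package's position is that the unadjusted
network must then earn its keep: `validate_vs_visitation()` correlates the
network against an independently observed visitation matrix, either the
raw r values (default) or the binary selection mask -- both modes exist
because either flattening is defensible and neither is canonical.

Derived outputs: `family_proportions()` distributes selected links over
plant-family-by-bee-family cells as proportions of all selected links
(totals are computed from unrounded proportions and rounded last, so
printed marginals can differ from sums of rounded cells in the third
decimal); `origin_ratio()` counts a bee group's selected links to native
prairie versus exotic/weedy plants (ratio > 1 means native affinity; a
zero denominator gives `Inf`, zero links overall `NaN`); and
`monthly_networks()` rebuilds the network within each month (pairing
site-by-year, months with fewer than three events skipped with a warning)
and aggregates selected links into plant-family-by-bee-family edge
weights -- bipartite edge lists, exported as tables rather than drawings.

## Calibration, recovery, and a known limitation

The acceptance suite ties the screening pipeline to its statistical
guarantees under the generator's default design:

* **Null calibration.** With all couplings zero, the fraction of defined
  cells with `p < 0.05` is required to sit within three binomial standard
  errors of 0.05 across 50 seeds -- the t-approximation is adequate even
  for 32-event Poisson series.
* **The sign filter does not halve the rate.**  If the null r distribution
  were symmetric, selected cells (`r > 0` and `p < 0.05`) would occur at
  about `alpha / 2`.  They do not: both series are non-negative and
  right-skewed, so coincident abundance spikes generate an excess of
  strong *positive* correlations (the null r distribution has a slightly
  negative median and a long right tail).  The suite asserts the
  symmetric-null expectation and the assertion fails honestly; the
  acceptance script reports the realized rate as `null_selected_rate`.
  This asymmetry is intrinsic to Pearson screening of count/cover data and
  is precisely why the network is validated against observed visitation
  rather than trusted on its own.
* **Recovery.** Planted effect sizes are chosen by an independent per-pair
  power oracle (a standalone simulation of one coupled pair under the
  generative mechanism, not the pipeline): at the oracle-validated
  `beta = 30` the full pipeline must recover at least 80% of planted links
  across 100 seeds, and at `beta = 80` restricted to May, at least 90% of
  recovered planted edges must fall in May across the monthly networks.
  `beta` is on the log link per unit proportional cover, so `beta = 30`
  against a plant with mean cover 0.03 multiplies a bee's expected count
  by about 2.5.

Problem sizes throughout the tests -- 50-seed null batches, 100-seed
recovery batches, 2000-draw Monte-Carlo oracles, exhaustive enumeration up
to 8 units -- were chosen as the smallest sizes at which the three-SE
bands are informative.

Known limitations: Pearson screening cannot distinguish association from
shared phenology (two taxa both peaking in July will correlate); the
compositional cover constraint induces weak negative dependence among
plant series; undefined cells make the effective number of tests vary
between datasets; and the dispersion F-test inherits ANOVA's sensitivity
to unbalanced, heteroskedastic distance distributions.  None of these are
corrected for -- they are properties of the plain procedure the package
implements.
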