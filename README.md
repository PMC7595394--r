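# prairienet

Bee community diversity and bee–plant co-occurrence networks for in-field
prairie strips.

## The problem

Sowing strips of reconstructed native prairie vegetation into 10–12% of a
row-crop field is a conservation practice aimed at sustaining wild bee
communities in agriculturally dominated landscapes. Evaluating it requires
a chain of community-ecology computations on paired strip/control field
surveys: bee abundance counts per monthly transect event, forb proportional
cover per species, land-cover composition of the surrounding landscape, and
an observed bee–plant visitation matrix. `prairienet` packages that chain
as tested, reusable R functions, together with a synthetic-data generator
with known ground truth so every stage can be verified without field data.

The stages:

* **Diversity** — Hill numbers ⁰D = S, ¹D = exp(H′), ²D = 1/Σpᵢ², with
  sample-size-based rarefaction (exact hypergeometric for q = 0, seeded
  Monte-Carlo subsampling for q = 1, 2), Chao1-style extrapolation, and
  bootstrap confidence bounds; Shannon landscape diversity
  H′ₛ = −Σ pᵢ ln pᵢ over land-cover categories and its non-crop transform.
* **Community comparison** — common/uncommon partitioning at a strict >1%
  study-wide relative-abundance boundary (with and without the pooled
  *Lasioglossum* (*Dialictus*) taxon), Bray–Curtis distances, the
  multi-response permutation procedure (MRPP: δ = Σ (n_g/N)·mean within-group
  distance, permutation T, A, p), and PCoA-based multivariate dispersion
  (betadisper-style distances to group centroids, ANOVA F) as an evenness
  proxy.
* **Co-occurrence network** — the core computation: every bee's abundance
  series correlated against every forb's cover series over paired
  (site, month, year) strip events; links selected by r > 0 and p < α with
  Benjamini–Hochberg adjusted p-values alongside; validation of the network
  against observed visitation; plant-family × bee-family proportion tables;
  native/exotic affinity ratios; monthly bipartite edge lists.
* **Pipeline** — `run_all()` orchestrates simulate → diversity → compare →
  network under one master seed and writes every artifact plus a JSON
  report.

## Worked example

```r
library(prairienet)

registry <- synthetic_registry()                       # 89 bees, 55 forbs
truth <- planted_scenario(seed = 1, n_pairs = 8, beta = 30)
sim <- generate_dataset(truth)
sim
#> Synthetic prairie-strip survey (seed 1)
#>   design: 4 sites x 2 treatments x 2 years x 4 months
#>   bees:   7538 individuals, 72 taxa
#>   plants: 55 taxa surveyed
#>   planted couplings: 8

d <- bray_curtis_matrix(sim$bees)
grp <- sub("\\|.*$", "", sub("^[^|]*\\|", "", attr(d, "Labels")))
mrpp(d, grp, n_perm = 999, seed = 1)
#> Multi-response permutation procedure
#>   delta = 0.3053 (expected 0.3677)
#>   T = -30.572, A = 0.1696, p = 0.001  (999 permutations)
multivariate_dispersion(d, grp)
#> Multivariate dispersion (distances to group centroids)
#>   group means: control = 0.2282, strip = 0.1972
#>   F = 7.141, parametric p = 0.009612

net <- select_links(build_cooccurrence(sim$bees, sim$plants, registry),
                    alpha = 0.05)
net
#> Bee-plant co-occurrence network
#>   89 bee taxa x 55 plant taxa over 32 sampling events (site,month,year)
#>   defined cells: 3740 / 4895
#>   selected links (r > 0, p < 0.05): 149
validate_vs_visitation(net, sim$visits)$r
#> [1] 0.1479524
```

Reading the numbers: the strip treatment separates community composition
(MRPP A = 0.17, p = 0.001 — within-treatment communities are 17% more
similar than chance) and lowers within-group dispersion (strip mean
distance-to-centroid 0.197 vs control 0.228, F = 7.1), i.e. strip
communities are more even. The network selects 149 positive bee–plant
links at α = 0.05 out of 3740 testable pairs, and those correlations agree
positively with the independently observed visitation matrix (r = 0.148
over all testable cells, consistent with the 8 planted couplings plus
noise). `family_proportions(net, registry)`, `origin_ratios(net, registry,
part)` and `monthly_networks(sim$bees, sim$plants, registry)` break the
selected links down by family, plant origin, and month.

A full orchestrated run:

```r
report <- run_all(run_config("out", seed = 1,
                             truth = synthetic_truth(seed = 1)))
```

writes `bees.csv`, `plants.csv`, `registry.csv`, `visits.csv`,
`landcover.csv`, `curves.csv`, `cooccurrence.csv`,
`family_proportions.csv`, `origin_ratios.csv`, `monthly_edges.csv`,
`landscape_summary.csv`, `config.json` and `report.json` into `out/`.

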