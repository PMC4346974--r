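# pollenprint

Infer which insect taxa visit a plant's flowers from the microbial
community left on the flower surface.

Flower-visiting insects carry on the order of a million microbial cells on
their body surfaces — more on larger-bodied insects — and deposit part of
this community on every flower they touch. Because insect surface
communities show a degree of species-specificity, the microbes remaining
on a flower act as a *fingerprint* of its visitors: candidate pollinators
can be ranked by how similar their surface communities are to the
flower's, and checked against direct visual observation. `pollenprint` is
for community ecologists and microbiome researchers who want to run this
analysis chain on 16S OTU tables, and to validate it against simulated
ground truth.

## What it computes

Given an OTU count table (samples × OTUs), sample metadata, and
optionally a taxonomy table and visitation records:

* **Filtering & standardization** — chloroplast-OTU exclusion
  (case-insensitive lineage match), a strict `> 200` reads-per-sample
  depth filter, and total-sum scaling to relative abundances.
* **Community comparison** — Bray–Curtis dissimilarity
  *d(x, y) = Σ|xₖ − yₖ| / Σ(xₖ + yₖ)*, seeded multi-restart NMDS
  (Kruskal stress-1), confidence ellipses of group centroids, and a
  PERMANOVA-style permutation test (pseudo-F, p = (1 + b)/(1 + B)) for
  community shifts.
* **Signature ("unique") OTUs** — an OTU is a signature of a group when
  its mean raw count there is ≥ 5× the maximum mean of every other group
  **and** its within-group coefficient of variation is < 300 %; per-OTU
  Kruskal–Wallis + pairwise Wilcoxon (Holm) compact letter displays.
* **The fingerprint ranking** — per insect taxon, mean ± sd Bray–Curtis
  dissimilarity over all (insect sample, flower sample) pairs, ranked
  ascending, and its Spearman comparison against visitation counts (after
  excluding visitors < 4 mm, ants, and spiders).
* **Cell counting** — Otsu + connected-components counting of
  DAPI-stained cells in micrographs, scaling of field counts to cells per
  individual, and the OLS regression of load on body weight with a 95 %
  slope CI.
* **Simulation** — a seeded generator of the whole causal chain (species
  profiles, weight-dependent loads, contact transfer, multinomial
  sequencing, Poisson visitation, synthetic DAPI images) that emits
  ground truth for every recovery test.

## Worked example

Simulate a laboratory contact experiment — three insect species of very
different body mass touching flowers, plus untouched control flowers —
and analyse it:

```r
library(pollenprint)

cfg <- simulation_config(seed = 11, transfer_fraction = 0.3,
                         species_weights_mg = c(650, 180, 80),
                         species_names = c("Xylocopa", "Bombus", "Apis"))
sim <- simulate_contact_experiment(cfg)
out <- run_contact_analysis(sim$table, sim$metadata, outdir = "demo",
                            seed = 11)
out$permutation_tests
#>    species n_touched n_control statistic p_value significant
#> 1     Apis         5         5  2.951681   0.006        TRUE
#> 2   Bombus         5         5  5.294051   0.006        TRUE
#> 3 Xylocopa         5         5 10.511874   0.006        TRUE
```

With 30 % of surface cells transferred per contact, every species shifts
its flowers' communities away from the controls, and the pseudo-F grows
with body mass (650 mg → F ≈ 10.5; 80 mg → F ≈ 3.0): heavier insects
deposit more cells. The unique-OTU report for flowers touched by the
large species recovers the planted signatures:

```r
head(subset(out$unique_otus[["touched_by_Xylocopa"]], passed), 5)
#>     otu_id focal_mean max_other_mean fold_ratio cv_percent passed
#> 23 otu_023        8.6            0.6      14.33       46.2   TRUE
#> 28 otu_028        7.0            1.4       5.00      145.7   TRUE
#> 31 otu_031       11.8            0.0        Inf       60.6   TRUE
#> 33 otu_033       20.6            2.2       9.36       50.5   TRUE
#> 34 otu_034       32.4            0.0        Inf       36.8   TRUE
sim$truth$signature_otus$Xylocopa
#> [1] "otu_034" "otu_184" "otu_153" "otu_144" "otu_113"
```

(`fold_ratio = Inf` marks OTUs absent from every other treatment.) A
field study compares the fingerprint ranking with visual observation:

```r
cfgf <- simulation_config(seed = 4, n_insect_species = 4,
                          replicates_per_group = 3, transfer_fraction = 0.3,
                          species_weights_mg = rep(300, 4),
                          species_names = c("Apis", "Eristalinus",
                                            "Phytomia", "Vespa"),
                          visitation_rates = c(10, 5, 2, 1))
simf <- simulate_field_study(cfgf, n_flowers = 5)
obs  <- simulate_visitation(cfgf, n_plots = 24, n_sessions = 8, seed = 44)
res  <- run_field_comparison(simf$table, simf$metadata, obs, "demo_field")
res$comparison
#> Fingerprint vs direct observation
#>   Spearman rho = 1.000 over 4 shared taxa
#>  insect_taxon mean_dissimilarity count fingerprint_rank visit_rank
#>          Apis             0.4504  1917                1          1
#>   Eristalinus             0.6492   922                2          2
#>      Phytomia             0.6835   392                3          3
#>         Vespa             0.6946   183                4          4
```

The most frequent visitor (`Apis`, rate 10/flower) is also the taxon most
similar to the flower communities (mean dissimilarity 0.45), and the
10×-rarer `Vespa` is the least similar — the fingerprint ranking
reproduces the visitation order exactly (rho = 1). See the vignette
(`vignettes/microbial-fingerprinting.Rmd`) for the model, its
assumptions, and what the simulator does and does not emulate.

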