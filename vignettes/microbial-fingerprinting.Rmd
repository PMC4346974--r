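---
title: "Inferring flower visitors from surface microbial communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring flower visitors from surface microbial communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pollenprint)
```

## The idea

Insects carry microbial cells on their body surfaces — typically on the
order of a million cells per individual, more on larger-bodied insects.
When an insect lands on a flower, part of this community is deposited on
the flower surface. Because surface communities show a degree of
species-specificity, the microbes left behind act as a *fingerprint* of
the visitor: an OTU table from a flower surface carries information about
which insect taxa have been visiting it. `pollenprint` implements this
inference chain end to end and, because field truth is rarely available,
ships a fully seeded simulator of the whole causal chain (insect
communities → weight-dependent loads → contact transfer → sequencing) so
every stage can be validated against known ground truth.

## The analysis chain

Starting from a raw OTU count table (samples × OTUs) and sample metadata:

1. **Chloroplast exclusion** (`exclude_chloroplast()`): plant-derived 16S
   reads are removed wherever the lineage contains "chloroplast",
   case-insensitively at any rank. This runs *before* the depth filter, so
   plant reads cannot rescue an under-sequenced sample; the pipeline
   manifest records sample/OTU counts before and after every filter.
2. **Depth filter** (`filter_min_reads()`): samples must have strictly
   more than 200 reads (a sample at exactly 200 is dropped).
3. **Standardization** (`standardize()`): total-sum scaling to relative
   abundances. A square-root-of-proportions option is provided for
   sensitivity analysis; total-sum is the default and the documented
   choice.
4. **Bray–Curtis dissimilarity** (`bray_curtis()`):
   $d_{ij} = \sum_k |x_{ik} - x_{jk}| \,/\, \sum_k (x_{ik} + x_{jk})$,
   bounded in [0, 1], not a metric (no triangle inequality is assumed
   anywhere).
5. **Ordination** (`nmds()`): non-metric MDS minimizing Kruskal stress-1
   with monotone regression, best of one principal-coordinate start plus
   20 random restarts, fully seeded. `group_ellipse()` summarizes group
   centroids with chi-square confidence ellipses of the mean.
6. **Community shift test** (`permutation_community_test()`): one-way
   PERMANOVA-style pseudo-F on the dissimilarity matrix with label
   permutation and the $(1+b)/(1+B)$ p-value estimator. The pseudo-F is
   computed from within- and between-group sums of squared
   dissimilarities; the observed statistic matches `vegan::adonis2`
   exactly and the permutation loop gives an explicit seed contract.
7. **Signature OTUs** (`select_unique_otus()`): an OTU is a signature of a
   group when its mean raw count there is at least **5×** the maximum mean
   in any other group, and its within-group coefficient of variation
   (sample sd / mean) is below **300 %**. Conventions: focal mean 0 never
   passes (CV undefined); absent everywhere else counts as infinite fold.
   The CV is computed within the focal group with the n−1 standard
   deviation. `per_otu_group_test()` adds Kruskal–Wallis + pairwise
   Wilcoxon (Holm) compact letter displays per OTU.
8. **The fingerprint ranking** (`rank_by_fingerprint()`): for each insect
   taxon, the mean (and sd) Bray–Curtis dissimilarity over *all*
   (insect sample, flower sample) pairs; taxa ranked by ascending mean.
   Averaging over all pairs (rather than per-flower means first) is the
   simplest scheme consistent with reporting a single mean ± sd per taxon;
   ties break lexicographically so the ranking is deterministic.
9. **Comparison with direct observation**
   (`compare_with_observation()`): Spearman rank correlation between
   visitation counts and negated mean dissimilarity over shared taxa.
   The correlation is an artifact-level summary — field studies compare
   the two approaches qualitatively — and taxa seen by only one approach
   are listed separately rather than silently dropped. Before the
   comparison, `filter_visitors()` excludes records below 4 mm body
   length, ants, and spiders (reasons recorded, nothing deleted).

`run_contact_analysis()` and `run_field_comparison()` orchestrate these
stages into reproducible report bundles whose `manifest.json` echoes every
threshold and seed actually used; re-running with the same inputs is
byte-identical, and replaying a manifest's settings reproduces the run.

## Cell counting and the weight–load model

`count_cells_in_image()` counts DAPI-stained cells as Otsu-thresholded
connected components of at least 4 px — the simplest defensible detector
for well-separated fluorescent spots; touching cells are not deblended,
and a uniform image returns 0 with a warning. `cells_per_individual()`
scales mean per-field counts by the filter/field area ratio and the
detachment/stained volume ratio (defaults: 5 mL detachment, 1 mL stained,
area ratio 2440). The default areas are *calibration* inputs chosen to
place per-individual magnitudes around $10^6$ cells; they are not
measurements, and per-individual values should be read as magnitudes.
`fit_weight_model()` fits load on weight by OLS on the raw scale (the
scale on which such loads are usually reported), with a t-based 95 % CI
for the slope and an optional log–log variant.

## What the simulator emulates

`simulation_config()` collects all free parameters. The defaults are the
package's reference conditions, chosen once:

| parameter | default | why |
|---|---|---|
| `n_otus` | 200 | scale of a small single-study amplicon table |
| `sequencing_depth_mean` | 1000 | reads/sample typical of small IonPGM runs |
| `body_weight_mg_range` | 65–650 mg | honeybee-to-carpenter-bee span |
| `load_slope` | 3400 cells/mg | mean simulated load ≈ 1.2 × 10⁶ cells |
| `flower_baseline_cells` | 2 × 10⁵ | flowers carry fewer cells than insects |
| `transfer_fraction` | 0.1 | free parameter; no published estimate exists |
| `replicates_per_group` | 5 | typical contact-experiment group size |
| `visitation_rates` | 10×…×1 ladder | spans a 10-fold frequency range |

Mechanics: one community profile per species, drawn from a Dirichlet over
the shared OTU pool; individuals jitter around their species profile
(Dirichlet, concentration 200 by default); loads follow the linear
weight model; a contact deposits `transfer_fraction × load` cells in the
insect's proportions onto the flower's baseline cells (deposits add
*cells*, not proportions, and are renormalized — physical transfer);
sequencing is multinomial at Poisson-jittered depth with no PCR-bias
term.

**Signature planting.** `signature_enrichment` acts on the Dirichlet
*concentration ratio*: a signature OTU's concentration is multiplied by
*e* in its host species and divided by *e* in every other species and in
the flower baseline. This models host-specific symbionts — frequent on
their host, almost absent elsewhere — which is what makes a taxon usable
as a fingerprint in the first place. With *e* = 1 all profiles are
exchangeable draws from one Dirichlet (the exact null). We deliberately
did not multiply the *realized* draw by *e*: under a sparse Dirichlet the
focal draw is often near zero and non-host shares are heavy-tailed, which
would make "planted" signatures undetectable by any method at realistic
depths — the plant would not be a plant.

**What the simulator does not emulate:** read-level errors, chimeras and
primer artifacts, PCR bias, compositional correlations among OTUs beyond
the Dirichlet, microbe dispersal from flowers back onto insects, temporal
turnover of visitation, and nectar chemistry. Passing the recovery tests
therefore shows the *inference chain* is sound under the stated
generative model, not that real communities satisfy that model.

## Numerical choices and degenerate inputs

* NMDS: `monoMDS` global model, primary ties, `smin = 1e-8`, stress-ratio
  stop at `1 - tol`; coordinates re-centered to the origin. Duplicate
  samples (zero dissimilarity) converge to coincident points up to the
  optimizer tolerance (~1e-3 relative). An independent
  isotonic-regression stress-1 implementation backs the optimizer-contract
  tests.
* Permutation test: all-identical samples give a degenerate pseudo-F that
  ties with every permutation; the test returns p = 1 by convention.
  Groups need ≥ 2 samples each.
* Compact letters: maximal cliques of the "not significantly different"
  graph, ordered by decreasing group mean, so "a" marks the highest
  group; untestable pairs (e.g. both groups constant) count as not
  different.
* DAPI spot placement enforces a minimum center separation of 4σ by
  rejection sampling (hard error when the packing is infeasible), so the
  planted count is unambiguous; recovery is exact on noise-free images
  for 0–200 cells.
* Problem sizes used by the validation suite: permutation calibration at
  500 replicates × 999 permutations (12 samples each); signature recovery
  at 100 seeded contact experiments; fingerprint recovery at 50 seeded
  field studies with 5 flowers and 3 samples per taxon; CI coverage at
  500 datasets of n = 48. These sizes give Monte-Carlo standard errors
  comfortably below the margins being asserted.

## Known limitations

The fingerprint confounds visitation frequency with body size: a rare,
large visitor deposits more cells than a frequent small one, so the
ranking reflects *deposited load*, not visits per se. The package exposes
this directly — holding rates fixed and scaling one species' weight ×10
measurably decreases its mean dissimilarity to flowers in the simulator.
Small insects (below the 4-mm observation cutoff) cannot be fingerprinted
at all. Real species-specificity of insect surface communities is weaker
than the simulator's well-separated profiles; on field data the ranking
should be read as a candidate list, not a quantitative visitation
estimate.
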