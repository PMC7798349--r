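# bilenet

Correlation and correlation-difference networks for bile acid ×
microbiome × metatranscriptome data.

`bilenet` is an R toolkit for gnotobiotic studies in which mice carrying a
defined 7-member gut bacterial consortium (capable of complete bile acid
metabolism, including 7α-dehydroxylation) are profiled across three data
layers — bile acid panels in cecum, liver and serum; 16S taxon counts; and
per-species cecal metatranscriptomes — under two treatments (control vs. a
berberine-supplemented diet). It is written for microbiome/multi-omics
analysts who start from count and concentration matrices and want the
integration statistics, not the upstream read processing.

## What it computes

**Correlation networks.** All layers are merged into a single samples ×
features table and every feature pair is scored within each treatment
group by Spearman's ρ (Pearson correlation of midranks). At the study's
group size (n = 6) p-values are **exact**: the null is enumerated over all
n! permutations of the observed midrank vectors (720 at n = 6), preserving
ties. Edges keep pairs with |ρ| ≥ 0.7 and p ≤ 0.05; at n = 6 the p-filter
is the binding one (the smallest |ρ| with p ≤ 0.05 is 0.886). Networks
export to edge-list TSV, GraphML and SIF for Cytoscape.

**Correlation-difference networks.** Pairs whose correlation changed
between treatments, tested either by the Fisher z statistic
z = (atanh ρ₁ − atanh ρ₂)/√(1/(n₁−3) + 1/(n₂−3)) (default, vectorized) or
by an exact label-permutation test that keeps each mouse's (x, y) pair
intact and enumerates all C(12, 6) = 924 group splits. Changed pairs at
p ≤ 0.01 form the difference network.

**Community statistics**, all implemented in-package (with `vegan` as a
test-time oracle): rarefaction without replacement (default 23,900
reads), Shannon diversity with an exact Mann–Whitney group test,
Bray–Curtis dissimilarity, NMDS (Kruskal stress-1 with isotonic
regression and a monotone descent), and ANOSIM with full enumeration or
999 permutations.

**Per-species differential expression**: TMM normalization (implemented;
`edgeR` is the test oracle), log2-CPM fold changes, an enumerated
permutation Welch-t per gene, BH FDR, and the |log2FC| > 0.58, p < 0.05
selection filter.

**Synthetic studies with planted truth.** A generator reproduces the
study conditions (2 × 6 mice, 7 taxa, ~53,000 ± 3,600 reads/sample, cecal
bile acid totals 1.29 vs 4.57 μmol/g, NB transcripts at dispersion 0.1)
and plants known effects: true log2 fold changes, and group-specific
gene–bile-acid rank correlations induced by a shared latent factor with a
numerically calibrated coupling. Every pipeline stage is tested against
this planted truth.

## Worked example

```r
library(bilenet)

cfg <- simulation_config(
  planted_corr = tibble::tibble(
    gene = "Bwads_g001", species = "Bilophila_wadsworthia",
    analyte = "DCA", compartment = "cecum", group = "berberine",
    target_rho = 0.9
  ),
  seed = 1
)
study <- generate_study(cfg)

total_bile_acids(study$bile_acids$cecum) |>
  dplyr::group_by(group) |>
  dplyr::summarise(mean_umol_g = mean(total))
#> # A tibble: 2 × 2
#>   group     mean_umol_g
#>   <fct>           <dbl>
#> 1 control          1.32
#> 2 berberine        4.58

combined <- combine_study(study)
combined
#> <feature_table> 12 samples x 1105 features (concentrations)
#>   features: bile_acid=48, taxon=7, transcript=1050
#>   groups:   control=6, berberine=6

net <- all_pairs_correlation(combined, "berberine") |>
  build_network(annotations = combined$features)
glance(net)
#> # A tibble: 1 × 7
#>   n_nodes n_edges n_components density n_negative_edges n_cross_type_edges
#>     <int>   <int>        <dbl>   <dbl>            <int>              <int>
#> 1    1105   22377            1  0.0367            11249               2067
```

The simulated control cecum holds ~1.3 μmol/g total bile acids and the
treated cecum ~4.6 μmol/g, matching the configured study conditions. The
berberine-group network keeps 22,377 of 609,960 pairs (3.7% — close to
the 3.3% null edge rate that the exact p ≤ 0.05 filter admits at n = 6,
plus the planted and compartment-driven structure); 2,067 edges cross
data layers. In this particular draw the planted Bwads_g001–DCA pair
realizes a sample ρ of 0.66 (exact p = 0.175) in the treated group versus
0.26 in controls — a deliberate illustration that at n = 6 even a
population ρ of 0.9 is recovered as an edge only about half the time.
Sub-networks (`subnetwork(net, "cecum|bile_acid|DCA")`), difference
networks (`differential_correlations()` + `difference_network()`), and
the full staged analysis (`run_pipeline()`, which writes TSV/GraphML/SIF
artifacts and a JSON manifest) build from the same objects; `tidy()`,
`glance()` and `autoplot()` methods cover the result types.

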