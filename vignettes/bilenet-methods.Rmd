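---
title: "Methods: correlation and correlation-difference networks for multi-omic gnotobiotic studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: correlation and correlation-difference networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bilenet)
library(dplyr)
```

# The analysis problem

`bilenet` implements an integrative analysis for gnotobiotic studies in
which mice carrying a defined 7-member gut bacterial consortium (two
*Bacteroides* species, *Parabacteroides distasonis*, *Bilophila
wadsworthia*, two *Clostridium* species and *Blautia producta* — a
community capable of complete bile acid metabolism, including
7&alpha;-dehydroxylation of cholic acid to deoxycholic acid) are profiled in
three data layers:

* **bile acid panels** (LC-MS/MS peak areas quantified against deuterated
  internal standards) in cecum, liver and serum;
* **16S taxon counts** from the cecal community;
* **per-species metatranscriptomes** (cecal RNA-Seq counts assigned to each
  consortium genome).

The scientific object of interest is not any single layer but the *network
of rank correlations* between features of all layers, computed separately
within each treatment group (control vs. a berberine-supplemented diet),
and the *correlation-difference network*: the set of feature pairs whose
correlation changed significantly between treatments. The package starts
from count/concentration matrices; alignment, OTU picking and spectral
processing are upstream and out of scope.

# The statistical core

## All-pairs Spearman correlation with exact small-n p-values

Every pair of features in the combined table (samples x features across all
layers) is scored by Spearman's rho, computed as the Pearson correlation of
midranks so that ties — frequent in count data with zeros — are handled
consistently.

At the study's group size (n = 6 mice per treatment) the usual t or
large-sample approximations for the p-value of rho are unreliable, so the
default p-value is **exact**: the null distribution is built by enumerating
all n! permutations of one feature's observed midrank vector against the
other's (720 permutations at n = 6). Enumerating the *observed* vectors
preserves the tie structure under the null. Two consequences worth knowing:

* the exact p can never be 0; its floor is 2/720 &asymp; 0.0028 for untied
  data at n = 6 (a correlation and its reversal always tie in |rho|);
* the attainable p-values are a discrete set. At n = 6 the smallest |rho|
  with p &le; 0.05 is 0.886 (p = 24/720 = 0.033); |rho| = 0.829 already has
  p = 42/720 = 0.058. A network filter of "|rho| &ge; 0.7 and p &le; 0.05"
  is therefore effectively a filter at |rho| &ge; 0.886 for untied data —
  the p-criterion, not the rho-criterion, binds.

Exact enumeration is limited to n &le; 9; beyond that the
t-approximation `t = rho * sqrt((n-2)/(1-rho^2))` is used. Null
distributions are cached by tie pattern, which makes the all-pairs scan of
hundreds of features essentially instantaneous.

## Network construction

Edges keep pairs with |rho| &ge; 0.7 **and** p &le; 0.05 (both defaults are
the analysis settings of the study design this package mirrors). The
magnitude filter deliberately retains negative correlations with the sign
stored per edge. No multiple-testing correction is applied to network
edges by default — the filter is a per-pair screen, not an inferential
claim; a BH-adjusted variant is available (`adjust_p = TRUE`). Topology
summaries (components, density, cross-layer edge counts, degrees) and
focal sub-networks (e.g. the radius-1 neighborhood of cecal DCA) are
computed on the filtered graph, and networks export to edge-list TSV,
GraphML and SIF for Cytoscape.

## Correlation-difference networks

Two tests for "did the correlation of pair (i, j) change between
treatments?" are provided:

* **Fisher z** (default): `stat = (atanh(r1) - atanh(r2)) /
  sqrt(1/(n1-3) + 1/(n2-3))` with a two-sided normal p. Fast and vectorized
  over all pairs, but approximate at n = 6; correlations at |rho| ~ 1
  (which occur with ties) are routed automatically to the permutation test
  because atanh diverges.
* **Label permutation** (exact at the study size): each mouse's (x, y) pair
  stays intact while group membership is permuted; all C(12, 6) = 924
  splits are enumerated and p = #{|&Delta;rho*| &ge; |&Delta;rho|}/924.

Changed pairs at p &le; 0.01 form the difference network. Pairs in which a
feature is constant within either group are excluded and logged.

### Power at n = 6 is structurally limited

A fact that shapes what these networks can show: the permutation null of
|&Delta;rho*| at n = 6+6 is both *discrete* (Spearman's rho at n = 6 takes
only 21 values, and the 924 splits produce typically ~27 distinct
|&Delta;| values, each split tying with its complement) and *wide*. In
simulations with a near-perfect treatment-only coupling (population rho
&ge; 0.95 vs. 0), the median exact difference p is about 0.1. The exact
test is valid but conservative: its null rejection rate at &alpha; = 0.01
is about 0.005–0.007 rather than 0.01, because the attainable p-values
jump in steps of 2/924 and tie heavily in the tail. The Fisher z test at
this size is mildly anti-conservative (~1.3% rejections at &alpha; = 0.01)
and has essentially no power for a 0.9-vs-0 change (its p for rho1 = 0.9,
rho2 = 0 at n = 6 is 0.071 > 0.01). Difference networks at these sample
sizes are hypothesis-generating screens, not calibrated discovery lists;
the package reports both tests so users can see the trade-off.

# Community diversity statistics

All diversity statistics are implemented in the package (the independent
implementations in `vegan` serve as cross-checks in the test suite):

* **Rarefaction** to a fixed depth (default 23,900 reads) by subsampling
  without replacement; shallow samples are dropped with a warning.
* **Shannon index** over positive proportions; natural log by default
  (base 2 available — rank-based group comparisons are base-invariant).
  Groups are compared by an exact Mann-Whitney test that enumerates all
  label assignments for total n &le; 12.
* **Bray-Curtis** dissimilarity, `1 - 2*sum(min)/(sum x + sum y)`.
* **NMDS**: Kruskal stress-1 minimized by alternating isotonic regression
  of configuration distances on dissimilarity ranks (ties ordered by
  current distance, the "primary" treatment) with a line-searched gradient
  step that only accepts non-increasing stress — so the stress trace is
  monotone by construction. Defaults: k = 2, 20 restarts (one classical
  scaling start plus 19 random), tolerance 1e-6, 300 iterations.
* **ANOSIM**: R = (mean between-group rank − mean within-group rank) /
  (n(n−1)/4) over jointly ranked distances, so R &isin; [−1, 1] with R = 1
  when all between-group distances exceed all within-group ones. The
  p-value is one-sided. When the number of distinct two-group labelings is
  at most `n_perm`, they are fully enumerated (20 at n = 3+3; 924 at 6+6)
  and p = #{R* &ge; R}/N; otherwise `n_perm` random permutations are used
  with the (+1)/(+1) convention so p is never 0.

# Differential expression

Each species' transcriptome is treated as its own composition and
normalized independently: TMM scaling factors (30% two-sided trim on
M-values, 5% on A-values, precision weights, reference library chosen by
upper-quartile proximity to the mean, factors re-centered to geometric
mean 1) followed by log2 counts-per-million with a 0.5 prior count. The
normalization is implemented in the package; `edgeR::calcNormFactors` is
used in the tests as an independent oracle (agreement to ~1e-3).

The per-gene test is a **permutation Welch t**: all 924 group splits are
enumerated at n = 6+6 and p = #{|t*| &ge; |t|}/924 (random splits with the
+1/+1 convention at larger n). Constant genes are flagged with p = 1.
Log2 fold changes are differences of group means of log2 CPM (treatment
minus control). BH FDRs are attached per gene; gene *selection* for heat
maps and network node sets uses the raw-p filter |log2FC| > 0.58 and
p < 0.05, with FDR reported alongside — the selection criterion and the
reporting convention are deliberately decoupled.

# The synthetic study generator

Because the real metabolomics and 16S tables of the motivating study
design are not desk-available, every stage is exercised against synthetic
studies with known truth. The generator's defaults *are* the study
conditions:

| quantity | default | basis |
|---|---|---|
| design | 2 groups x 6 mice (3M/3F) | study design |
| taxa | the 7 consortium members | study design |
| 16S depth | Normal(53,000, 3,600) reads | reported sequencing depth |
| transcripts | NB, dispersion 0.1, 150 genes/species, lognormal means | typical RNA-Seq moments |
| cecal total bile acids | 1.29 (control) vs 4.57 (treated) umol/g | reported totals |
| cecal lognormal sdlog | 0.15 control / 0.40 treated | reported total CVs (0.106/1.29, 1.42/4.57) |
| liver/serum means | group-invariant | reported compartment result |

Treatment multiplies every cecal analyte mean by 4.57/1.29; per-analyte
control means are a fixed registry chosen once to sum to 1.29 umol/g with
a realistic composition (unconjugated primaries dominant, secondary bile
acids present, taurine conjugates near-fully deconjugated, trace
sulfates). Sex is carried in the metadata but has no simulated effect (the
motivating study found none).

**Planted effects.** DE genes receive a true log2 fold change in the
treated group. Group-specific gene–bile-acid correlations are planted via
a shared per-sample latent factor z ~ N(0,1): the gene's NB log-mean gains
`|beta| * z` and the analyte's log-concentration gains `sign(beta) * beta *
z` (mean-preserving on the analyte side so bile acid totals stay
calibrated; deliberately *not* mean-corrected on the count side, where a
shrinking mean would collapse low-z samples onto tied zeros and cap the
attainable correlation). The coupling is active only in the configured
group, so the other group's correlation is centered at zero. `beta` is
calibrated by bisection against a large-sample (n = 10,000) Monte Carlo of
the same mechanism — a latent-factor construction was chosen over a copula
on observed values because it respects count noise at n = 6.

What the generator does *not* emulate: compositional coupling between
taxa and transcripts, batch effects, library-size confounding with
treatment, analyte detection limits, or missingness (undetected analytes
are zeros by contract). Passing recovery tests therefore demonstrate the
statistical machinery, not robustness to those real-data pathologies.

## What recovery at n = 6 can and cannot achieve

With planted pairs at population Spearman 0.9, the sampling distribution
of rho at n = 6 gives P(sample rho &ge; 0.886) &asymp; 0.5 — and 0.886 is
the effective edge threshold (see above). Mean per-group recall of planted
edges is therefore &asymp; 0.5–0.6, for any implementation; it is a property
of the statistic at this sample size, not of the code. Likewise, with 200
null features there are ~20,000 null pairs and the null edge rate equals
the attainable p-mass below 0.05 (24/720 &asymp; 3.3%), so a per-group
network carries hundreds of chance edges against at most 10 planted ones —
global precision against all null pairs is bounded near 1–2% no matter the
method. The package's recovery experiment
(`evaluate_network_recovery()`) reports both quantities honestly rather
than redefining them; the meaningful claims at this design size are
*enrichment* (planted pairs are recovered at ~15x the null edge rate) and
*specificity of the mechanism* (the non-planted group's correlations stay
centered at zero).

# Bile acid quantitation

Single-point internal-standard quantitation with response factor 1:
`conc = (area / IS area) * IS amount / sample mass`, nmol converted to
umol (the assay spikes d4-labeled standards at 100 nmol/ml; per-analyte
response factors are accepted as configuration). Class summaries
(conjugation, primary/secondary origin, sulfation) conserve mass exactly
by construction. Units are per g dry matter for cecum and liver and per L
for serum; panels never mix compartments.

# Numerical and design choices

* **Canonical order**: files are feature x sample (the bioinformatics
  convention); in memory everything is samples x features with samples
  sorted by id. Combined tables prefix feature ids with
  compartment/species to guarantee uniqueness.
* **Missing values** are rejected at read time; undetected analytes must
  be written as 0.
* **Permutation p conventions**: full enumeration uses p = count/N with
  the observed labeling included (count &ge; 1, so p > 0); random sampling
  uses (count+1)/(n_perm+1). Applying the +1/+1 correction to a full
  enumeration would double-count the observed labeling and bias p upward.
* **Exact-test tie tolerance**: comparisons use a 1e-12 slack so that
  equal-by-construction statistics computed along different floating-point
  routes still count as ties.
* **Degenerate inputs**: constant features are skipped in correlation
  scans (logged); constant genes get p = 1 with a flag; a constant feature
  within a permuted split contributes rho = 0 to that split.
* **Matched mice**: cross-compartment correlations assume liver/serum/cecum
  measurements are matched per mouse — required for any correlation at
  n = 6.
* **Problem sizes in the tests**: unit tests run the same machinery at
  reduced scale (4–8 genes per species, 60–200 null features, 5–60
  replicates); the acceptance checks use the full stated designs (200
  random vectors for the Spearman oracle, 5,000 null pairs for the
  difference-test calibration, 50 studies for recovery, 2,000 genes for DE
  calibration). These sizes were chosen to estimate each quantity to well
  within the asserted tolerance.

# A worked example

```{r example, eval = FALSE}
cfg <- simulation_config(
  planted_corr = tibble::tibble(
    gene = "Bwads_g001", species = "Bilophila_wadsworthia",
    analyte = "DCA", compartment = "cecum", group = "berberine",
    target_rho = 0.9
  ),
  seed = 1
)
study <- generate_study(cfg)
run <- run_pipeline(study, pipeline_config(seed = 1), "run1")
pipeline_report("run1")

combined <- combine_study(study)
net <- all_pairs_correlation(combined, "berberine") |>
  build_network(annotations = combined$features)
glance(net)
autoplot(subnetwork(net, "cecum|bile_acid|DCA", radius = 1))
```

# Known limitations

* Exact Spearman p-values stop at n = 9 (n! enumeration); the t
  approximation takes over silently under `method = "auto"`.
* The Fisher z difference test is approximate at small n; the exact
  permutation alternative is conservative (see above). Neither gives a
  calibrated-and-powerful test at n = 6 — that is a property of the design
  size.
* NMDS minimizes stress-1 locally; 20 restarts make the best-of-restarts
  stress reproducible in practice, but global optimality is not
  guaranteed.
* The generator plants correlations pairwise via independent latent
  factors; it does not simulate whole correlated modules.
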