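---
title: "Methods: viability-screen scoring and functional fingerprinting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: viability-screen scoring and functional fingerprinting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenprint)
```

`screenprint` analyzes arrayed loss-of-function viability screens:
384-well plates in which each library well carries an siRNA pool against
one gene, read out by a luminescent ATP assay (relative light units,
RLU) as a proxy for viable cell number. Its purpose is twofold: score
individual genes for viability phenotypes, and compare whole cell
populations — e.g. mesenchymal stromal cells (MSCs) against fibroblasts
— by their kinome-wide loss-of-function "fingerprints". This vignette
describes the statistical model, the tunable parameters, the generative
simulator used for validation, and the design choices made where the
underlying conventions are genuinely open.

## Plate model

Plates follow the letter-row convention (rows A–P, columns 1–24,
`"G04"`). The default kinome layout places library siRNAs in columns
5–24 (320 wells per plate, filled row-major in gene order, so a
778-gene kinome occupies 3 plates with 320 + 320 + 138 library wells),
negative controls (Rluc, an siRNA with no human target) at G04–J04,
positive controls (UBC, strongly viability-reducing) at F03–I03. The
positions of untreated (no-reagent) wells are not fixed by any assay
convention; the package defaults to K03–N03 and keeps them
configurable, because the relative-viability denominator pools
untreated and negative-control wells. All remaining wells in columns
1–4 are empty. Range notation such as "G04–J04" is read as consecutive
rows at a fixed column.

## Gene scoring

Scoring runs in a fixed order; each step exists for a reason and the
order matters:

1. **Relative viability.** Each well is divided by the mean RLU of the
   plate's untreated and negative-control wells (configurable to
   negative controls only). This is the fraction-of-control scale on
   which hit thresholds are defined.
2. **Multiplicative normalization.** Genes act multiplicatively on cell
   number, so each well is scored as `log2(RLU / s_p)` with the plate
   scale factor `s_p` the *median* RLU over library wells. The median
   is robust to the screen's own hits; every plate's library log2
   ratios have median 0 by construction, and all downstream statistics
   are invariant to per-plate scale factors (plate effects cancel).
3. **Variance adjustment by experiment.** Replicate screens can differ
   in dynamic range (transfection efficiency, reagent batches). Within
   each replicate screen the log2 ratios are divided by the MAD (scaled
   by 1.4826) of its library wells, bringing every experiment to robust
   scale 1. The MAD is used rather than the sd so that the heavy lower
   tail of true phenotypes does not inflate the rescaling; a plain-sd
   option exists behind a flag. The operation is idempotent.
4. **Replicate summarization.** The median across replicate screens
   (equal to the mean for duplicates, robust beyond).
5. **Plate-mean z-scores.** `z = (x − mean)/sd` over the summarized
   values of each plate's *library* genes. Control wells are excluded
   from the plate statistics: the positive controls are far off-scale
   and would bias both moments. Whether z-scores should be computed
   before or after summarization is not dictated by the scale-invariance
   argument; the package follows the order above (summarize, then
   standardize), matching the sequence in which the steps are usually
   stated.

Two normalization products are kept deliberately: z-scores and relative
viability for hit scoring, and per-plate *control-normalized* log2
values (`log2(RLU / mean neg-control RLU)`, not variance-adjusted) for
fingerprinting. Zero-RLU library wells get relative viability 0 and are
excluded from log-scale statistics with a warning.

## Quality control

- **Z'-factor**: `1 − 3(σ_pos + σ_neg)/|μ_pos − μ_neg|` on raw RLU
  within a plate; > 0.5 marks an excellent screening window. Z' is
  invariant under common positive affine transforms of the control
  values, so raw RLU and relative viability give identical results.
  Because per-screen summaries of Z' could be either means or medians,
  the QC report emits per-plate values plus both summaries.
- **Profile correlations**: Pearson r between per-gene profiles, at
  three levels of the repetition hierarchy — technical (single-replicate
  profiles of one preparation), preparation (summarized profiles of two
  preparations of one donor), donor (summarized profiles across
  donors). Technical-level correlations intentionally use unsummarized
  profiles; summarization would hide the quantity being checked.
- **QQ tail analysis**: ordered z-scores against normal quantiles
  `Φ⁻¹((i − 0.5)/n)`, counting deviations beyond ±`delta` from the
  *identity* line (the inputs are already standardized, so no
  quartile-fit line is needed). `delta = 0.5` is a package choice: large
  enough to ignore ordinary sampling wiggle at n ≈ 800, small enough to
  count a planted tail. A healthy screen of a viability library shows
  lower-tail excess (more growth-impairing phenotypes than normal) and
  little upper excess.

## Hit calling

Candidates are genes whose mean summarized relative viability across
the selected samples is ≥ 1.20 (increase) or ≤ 0.75 (decrease),
inclusive. Inclusivity follows the "at least" phrasing of such
thresholds; symmetry is assumed for the decrease bound. The candidate
set is monotone in the thresholds. The averaging sample set is an
explicit argument because screens of different cell classes should not
silently be pooled.

## Fingerprinting

The fingerprint matrix holds replicate-summarized control-normalized
log2 values, genes × samples, with cell-class annotations.

- **Grouping before testing.** Preparations of the same donor are not
  biologically independent; their profiles are averaged (unweighted
  mean — the combination rule is a package choice) into one per-donor
  profile. With the default design this yields N = 2 MSC and N = 4
  fibroblast profiles.
- **Per-gene tests.** Unpaired two-tailed *Student* (equal-variance)
  t-tests, df = n1 + n2 − 2 — Student rather than Welch because that is
  the test named for this analysis style, and at N = 2 per-gene variance
  estimates are too unstable for Welch to help. A gene is *selected*
  when p ≤ α (default 0.05). No multiple-testing correction is applied
  by default — the analysis is explicitly explorative and a
  fingerprint panel is validated as a set, not gene-by-gene — but a
  Benjamini–Hochberg option exists behind a flag. The p ≤ α rule is
  flagged as an assumption: it is the natural reading of "identified by
  t-test", but other filters (fold-change, cluster membership) would
  also be defensible.
- **Effect size and power.** Cohen's `d = |Δmean|/s_pooled`; post-hoc
  power from the noncentral t distribution with
  `ncp = d√(n1·n2/(n1+n2))`: `P(|T'| > t_{1−α/2,df})`. Power equals α
  exactly at d = 0 and is strictly increasing in d and the group sizes.
  Power is computed per gene by default; a cluster-mean option exists
  because a per-cluster summary is sometimes wanted, but per-gene is
  the less ambiguous default.
- **Clustering.** Both axes are clustered agglomeratively with distance
  1 − Pearson r and average linkage — the standard settings of the
  heatmap tools used for this kind of matrix. Leaf order is then
  optimized exactly (a dynamic program over the dendrogram that
  minimizes the summed distance between adjacent leaves, among all
  2^(n−1) compatible orderings); the implementation is tested against
  brute-force enumeration. The optimization is O(n³) and intended for
  panel-scale matrices (tens of genes, a handful of samples); on
  thousands of genes it dominates runtime and can be disabled.
  Zero-variance rows/columns have no defined correlation and are
  assigned the maximal distance 2 to all others, with a warning. The
  flat sample partition is a dendrogram cut at k clusters (default 2,
  the MSC-vs-fibroblast question).

## The simulator

`simulate_screen()` draws complete screens from an explicit generative
model so that every pipeline stage can be validated against ground
truth. A library well of gene *g* in class *c* reads

`RLU = B_p · 2^(θ_g + Δ_g[c] + ν_donor + ν_prep + ν_screen + ε_well)`

- **Effects** `θ_g` come from a three-component mixture: 10% "kill"
  genes ~ N(−0.9, 0.35²) log2 (the heavy lower tail a viability screen
  of kinases shows; ≈ 9% of genes fall below 75% viability), 3%
  enhancers ~ N(+0.35, 0.12²), the rest near-null N(0, 0.05²).
- **Noise** is a four-level hierarchy of per-gene deviations — donor
  (σ = 0.17), preparation (0.08), replicate screen (0.11), well
  (0.08), all log2 — the minimal structure that can produce three
  distinct correlation levels (technical > preparation > donor).
  Control wells share one reagent-level per-screen deviation (one
  reagent batch per screen) instead of per-gene screen noise; untreated
  wells carry cells but no reagent-level noise. Empty wells are
  simulated like untreated wells (the model does not emulate
  true zero-background luminescence).
- **Controls and plates.** The positive-control effect is −2.74 log2
  (≈ 15% viability), making the UBC wells clearly separated from the
  negative controls, and plate baselines are log-normal with log2 sd
  0.25 around a typical 2·10⁴ RLU.
- **Planted panel.** 35 genes receive class-specific offsets, |Δ|
  uniform in [0.4, 0.9] log2, split into a stronger-in-MSC and a
  stronger-in-fibroblast cluster; the stronger effect is always the
  more viability-reducing one.
- An **edge-effect** amplitude (default 0) can add a log2 bump to the
  outermost well ring as a robustness stressor; the default model has
  no spatial structure, and the pipeline deliberately contains no
  spatial correction.

`expected_profile_correlation()` is the closed-form calibration oracle:
`r = S/(S + V)` with `S` the across-gene variance shared by two
profiles and `V` the per-profile noise that differs between them.
Shared variance counts the effect-mixture variance, the planted
within-class offsets when both profiles are the same class, and every
hierarchy level the profiles have in common (technical replicates share
donor *and* preparation deviations — they are the same biological
material). `V` counts screen + well variance (halved after duplicate
summarization), the between-plate part of the control-normalization
noise (the negative-control mean is estimated from 4 wells per plate),
and the preparation/donor variances where the profiles differ.
Screen-constant reagent shifts cancel in across-gene correlations and
are not counted. With the defaults the oracle gives r ≈ 0.88 at the
technical level and ≈ 0.70 at the summarized donor level, matching
Monte-Carlo simulation within ±0.03.

What the simulator does *not* emulate — and hence what passing tests do
not show about real screens: off-target effects and reagent-specific
biases, spatial plate artifacts (unless the stressor is switched on),
non-Gaussian well noise, uncertainty in the class labels themselves,
and any biology linking genes (planted differential genes are drawn
independently, unlike a real signaling-pathway cluster).

Two calibration facts are worth stating plainly because they follow
from the model rather than from any tuning. First, the per-plate
control normalization injects a small but real extra variance into
every fingerprint value (reagent-level deviation of the control pool,
plus the 4-well control-mean noise); this pushes the realized
within-class profile sd to ≈ 0.22 and caps the mean per-gene power for
the default planted panel (|Δ| ∈ [0.4, 0.9], N = 2 vs 4, α = 0.05) at
about 0.75 — the default panel is deliberately not fully recoverable,
as in any realistically powered small-n screen. Second, technical
replicates of one preparation share all biological variance levels, so
their expected correlation (≈ 0.87) exceeds the donor-level one
(≈ 0.69) by construction.

## Numerical choices and degenerate inputs

- Oracle-matching statistics (Z', Pearson r, plate z-scores, t) are
  required to agree with brute-force two-pass computations to 1e-12.
- Degenerate inputs abort with named coordinates rather than producing
  NaN: zero control means, zero plate scale factors, zero MAD, constant
  plates (sd 0), constant profiles (undefined correlation), zero pooled
  variance (in per-gene panel testing the gene is flagged, excluded and
  warned about instead, so one flat gene cannot abort a 778-gene
  panel).
- Ties: hit tables sort by ascending mean viability with gene id as
  tie-break; panels sort by p then gene id; the optimal-leaf-ordering
  DP resolves cost ties by first index, so results are deterministic.
- TSV numerics are written with 17 significant digits so that write →
  read round-trips are exact.

## Problem sizes used in the test suite

The suite validates statistical behavior at sizes chosen to balance
sensitivity against runtime: 25 seeds for calibration means and
recovery rates (full 778-gene, 7-sample, duplicate screens where the
quantity requires them; single- or two-sample screens where it does
not), 100 plates for the Z' floor, 100 random instances per
brute-force oracle, 100,000 Monte-Carlo replicates per point for the
power curve, and 10,000 null genes for the type-I error of the
small-n t-test.

## Known limitations

- 384-well plates only; no barcode/LIMS integration.
- No spatial (B-score/median-polish) correction — screens with strong
  edge effects need preprocessing elsewhere.
- No off-target modeling or siRNA-level deconvolution; the pipeline
  stops at the gene level.
- The differential panel is explorative (no multiple-testing correction
  by default) and its p ≤ α selection rule is an assumption, flagged
  above.
- Network construction and enrichment analysis of the exported panel
  are out of scope; `panel_gene_list()` writes a plain gene list for
  external tools.
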