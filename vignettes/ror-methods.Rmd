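---
title: "PAM50 subtyping and risk-of-recurrence scoring: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PAM50 subtyping and risk-of-recurrence scoring: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ror50)
```

## The problem

The PAM50 panel assigns early breast cancers to one of five intrinsic
subtypes — basal-like, HER2-enriched, luminal A, luminal B, normal-like —
by nearest-centroid classification on 50 genes, and summarizes prognosis as
a continuous risk-of-recurrence (ROR) score on a 0–100 scale. In clinical
practice the assay runs on RNA from macrodissected FFPE tissue, i.e. tissue
enriched for tumor cells by a pathologist. Research cohorts, by contrast,
usually profile fresh-frozen *bulk* biopsies whose normal-cell content is
uncontrolled. `ror50` implements the research-based scoring pipeline for
both kinds of input, the concordance statistics for comparing two assays of
the same cohort, and a tumor-purity simulator that reproduces the key
artifact of bulk profiling: inflation of the normal-like subtype and
deflation of ROR in low-purity samples.

## The scoring pipeline

Given a genes × samples matrix of log2 expression restricted to the PAM50
panel, the pipeline runs four steps.

**1. ER status from ESR1 bimodality.** ESR1 expression in breast tumor
cohorts is strongly bimodal. A two-component one-dimensional Gaussian
mixture (unequal variances, fitted with `mclust`) is fitted to the cohort's
ESR1 values; the component with the higher mean defines ER-positive, each
sample is labelled by posterior probability, and the decision threshold is
the equal-posterior point between the component means. The fit is rejected
as "unimodal" when a component carries < 5% of samples or the means are
< 0.5 log2 units apart — then ER status must be supplied externally (IHC),
via `er_call_from_status()`. Degenerate inputs (near-zero spread) are
rejected before the EM ever runs, because EM on constant data does not
converge. The fit is deterministic given the seed.

**2. ER-balanced 60/40 centering.** Nearest-centroid classification is
sensitive to how genes are centered: centering on the plain cohort mean
implicitly assumes the cohort has the same ER composition as the series on
which the centroids were trained (~60% ER-positive). A cohort with ~80%
ER-positive tumors would be centered toward its luminal bulk, biasing every
correlation. Instead, each gene is centered on
`0.6 * mean(ER+) + 0.4 * mean(ER−)`, which reconstructs a 60/40-balanced
reference point regardless of the cohort's actual ER mix. The weight `w`
is exposed (`weighted_center(..., w = 0.6)`) but 0.6 is the method's
constant, not a tuning dial. The per-gene reference is returned as a
`centering_reference` so new samples can be centered consistently
(`apply_centering()`).

**3. Subtype by centroid correlation on 46 genes.** Each centered sample
vector is Pearson-correlated with the five subtype centroids. Four genes
(BIRC5, CCNB1, GRB7, MYBL2) are excluded from classification, leaving 46;
this reduced panel is used both for the subtype call and for the four
correlations that enter ROR. The call is the argmax over the five
correlations — normal-like included — with runner-up and margin reported.
Exact ties (probability ~0 on real data, but possible on constructed
input) resolve by the fixed order Basal, Her2, LumA, LumB, Normal and are
flagged.

**4. Proliferation and ROR.** The proliferation score is the unweighted
arithmetic mean of 18 proliferation genes' centered log2 values (see
`proliferation_genes()`; legacy symbols ORC6L/KNTC2/CDCA1 are ORC6, NDC80
and NUF2). The continuous score is

ROR = 54.7690 · (−0.0067·Basal + 0.4317·HER2 − 0.3172·LumA + 0.4894·LumB
  + 0.1981·prolif + 0.1133·T + 0.8826)

with Basal/HER2/LumA/LumB the centroid correlations (the normal-like
correlation never enters), prolif the proliferation score, and T = 1 for
tumors larger than 2 cm. Risk categories depend on node status: cutoffs
40/60 for node-negative patients, 15/40 with 1–3 positive nodes, and
automatic high risk with 4 or more. The boundary convention is half-open —
low ≤ lower cutoff < intermediate ≤ upper cutoff < high — which is the only
convention consistent with published categorized scores straddling the
boundaries (39.94 → low, 60.06 → high). Raw scores are reported unclipped;
0–100 is treated as the calibrated range, not a transform, and a `clipped`
flag marks excursions.

```{r anchors}
res <- subtype_result_from_correlations(matrix(0, 1, 5))
clin <- data.frame(sample_id = res$sample_id, size_gt_2cm = FALSE,
                   node_class = factor("pN0",
                                       levels = c("pN0", "pN1_3", "pN4plus")))
ror_score(res, setNames(0, res$sample_id), clin)$ror  # 54.7690 * 0.8826
```

## The packaged centroid set is synthetic

The published PAM50 centroid matrix is not redistributable here, so the
package ships a **synthetic** centroid set
(`inst/extdata/pam50_centroids_synthetic.tsv`, built by
`data-raw/make_synthetic_centroids.R`). It encodes the qualitative module
structure of the real centroids — proliferation genes high in basal-like
and luminal B and lowest in normal-like; the ER/luminal module high in
luminal tumors; the ERBB2/GRB7 amplicon defining HER2-enriched; basal
keratins (KRT5/14/17, SFRP1) shared by basal-like tumors and normal
epithelium — with a small fixed jitter to avoid collinearity, on a
log-ratio scale of roughly ±2. Its values were designed once from that
structure and never adjusted afterwards. Everything the package computes is
therefore methodologically faithful, but absolute numbers obtained with the
synthetic set (correlations, scores) are not comparable to assay output on
real tumors; to score real data, pass the published centroid file to
`load_centroids()` — the loader accepts any TSV in the documented layout,
including one with legacy gene symbols.

## The simulator

`simulate_cohort()` generates a paired cohort with ground truth; its
defaults are the study conditions the package is designed around, not knobs:

* 94 samples; subtype mix 14% basal-like, 6% HER2-enriched, 52% luminal A,
  28% luminal B, 0% normal-like (real tumors of the normal-like class are
  rare and their existence is debated; the simulator treats every
  normal-like *call* as a contamination readout);
* ER status tied to subtype (luminal ⇒ ER-positive), matching a ~80%
  ER-positive cohort; the `er_pos_fraction` field tops up ER-positive
  labels among non-luminal samples only if the luminal mass falls below it;
* 38% of tumors > 2 cm; node classes 68% pN0, 27% pN1–3, 5% pN4+ (tumors
  with 4–9 positive nodes belong to the always-high-risk class);
* macro purity uniform on [0.85, 1]; bulk purity Beta(4, 1.5) (mean ~0.73
  with a long lower tail); per-gene noise SD 0.3 log2 units; bulk platform
  distortion slope ~ N(1, 0.1) and offset ~ N(0, 0.3) per gene.

Per sample with true subtype *k*, a tumor profile `t = centroid_k + noise`
and a normal profile `n = normal_centroid + noise` are drawn once and
shared by both assays: `macro = p_m·t + (1−p_m)·n`, and
`bulk = slope·(p_b·t + (1−p_b)·n) + offset + noise`. Mixing is affine in
log2 space — a deliberate simplification, since centroids exist only in
log-ratio space and linear-scale mixing would require an arbitrary inverse
transform; `linear_mix = TRUE` mixes on the 2^x scale for sensitivity
checks. The normal-tissue profile is the normal-like centroid itself: it
is the only in-scope representation of normal epithelium. A single seeded
stream drives every draw, so runs are bit-reproducible.

What the simulator does **not** model: FFPE RNA degradation, probe-level
counting noise, lymphocyte infiltration, intratumor heterogeneity beyond
i.i.d. Gaussian gene noise, and any real platform's nonlinearities. Passing
simulation tests therefore demonstrates the pipeline's internal
correctness and the purity mechanism, not equivalence to any clinical
assay on real tissue.

`contamination_curve()` isolates the purity effect for one subtype: *m*
replicates per purity on a descending grid, centered with a reference
learned from a background cohort under the same configuration (using the
simulator's true ER labels rather than a refitted mixture, so ER-call noise
cannot leak into the curve), scored with T = 0. On the defaults, mean ROR
falls monotonically with purity and the normal-like call rate switches on
sharply below ~50% purity.

## Concordance analyses

`score_agreement()` reports the squared Pearson correlation (r² is defined
as the square of the correlation coefficient, not a regression R²), the
mean absolute difference, and the signed difference range under the fixed
convention A − B. `subtype_confusion()` cross-tabulates calls with
concordance = trace/total. `risk_group_discordance()` lists samples whose
category changed between two result sets (refusing to compare results
categorized under different threshold tables) sorted by signed score
difference, optionally restricted to the clinically test-eligible subset
(ER+/HER2−/pN0) via a named preset — a preset rather than a free-form
filter, so the selection is auditable. `per_gene_cross_correlation()`
correlates each gene across platforms, flags genes at or below r = 0.75,
and marks the proliferation signature; zero-variance genes yield a flagged
`NA` rather than an error, since one flat gene should not abort a
50-gene report.

## Numerical choices and degenerate inputs

* Pearson correlations use `stats::cor`; a sample with zero variance
  across the 46-gene panel is an error naming the sample.
* Missing panel genes are a hard error by default; `allow_missing = TRUE`
  computes on the intersection and records `n_genes_used`, because silent
  subsetting changes scores.
* The 18-gene proliferation mean never falls back to fewer genes.
* TSV round-trips are exact to 1e-6 (six-decimal formatting).
* Reports written as JSON embed the package version, a configuration hash
  and the seed.

## Problem sizes

The test suite and the acceptance script run cohorts of 94 samples (the
structure the defaults emulate), 20 seeds for recovery checks, 50 seeds
for the normal-like inflation rate, and 100 replicates per purity point on
a 9-point grid — sizes at which the Monte-Carlo properties they assert are
stable to well under the asserted margins.

## Known limitations

* With the synthetic centroids, absolute ROR values are internally
  consistent but not calibrated to any clinical assay's scale.
* The ER mixture call needs a genuinely bimodal cohort (≥ 6 samples, both
  classes present); single-class cohorts must use external ER status.
* The vendor assay's proprietary algorithm is not reimplemented; where its
  outputs appear they are treated as given reference columns.
* Survival outcomes are out of scope: the package scores risk, it does not
  validate prognosis.
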