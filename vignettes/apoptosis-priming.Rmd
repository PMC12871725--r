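---
title: "Apoptosis-priming analysis of human DRG in diabetic painful neuropathy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Apoptosis-priming analysis of human DRG in diabetic painful neuropathy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drgpn)
```

## The scientific problem

Sensory neurons of the human dorsal root ganglion (DRG) are lost in diabetic
painful neuropathy (DPN): histologically this appears as Nageotte nodules,
the residue of dead neurons. `drgpn` implements a single-nucleus RNA-seq
analysis chain built to ask, at per-nucleus resolution, *which* neuronal
subtypes are primed to die, *how* cell-type composition shifts from Control
through Diabetic to DPN donors, and *which* ligand–receptor signals onto
neurons change along the way. Because donor-level data of this kind are
access-controlled, the package carries a first-class synthetic cohort
generator that reproduces the study design (14 Control / 10 Diabetic / 6 DPN
donors, eight major cell classes, 22 neuronal subtypes) with planted ground
truth, so every downstream stage is testable end to end.

## The per-nucleus priming score

The core quantity is a composite **apoptosis trigger score** per nucleus:

$$T = S_\text{apoptosis} + S_\text{p53} + S_\text{DNA repair} + S_\text{UPR} - S_\text{survival}$$

where each $S$ is a gene-module score on log-normalized expression: the mean
expression of the module genes minus the mean of expression-matched control
genes. Controls are drawn by ranking all genes on mean expression, cutting
the ranking into `n_bins = 24` equal-size bins, and sampling `n_ctrl = 100`
control genes per module gene from the module gene's bin (excluding module
genes; without replacement when the bin allows it, with replacement
otherwise). Sampled controls are pooled *as a multiset* — a gene drawn twice
is weighted twice — which keeps the estimator an unweighted mean over draws;
pooling conventions differ between implementations, so ours is pinned by an
oracle test. Subtracting bin-matched controls removes the per-cell depth and
mean-expression components, which is why a uniform shift of one cell's
profile leaves its score unchanged (an invariant the tests assert at 1e-10).

The survival module is anchored on eleven canonical anti-apoptotic and
IAP-family genes (BCL2, BCL2L1, BCL2L2, BCL2A1, MCL1, XIAP, BIRC2, BIRC3,
BIRC5, BIRC6, CFLAR). NF-κB-linked regulators are sometimes added to such
modules; because no canonical list exists we default to the eleven genes
only, and the module is an ordinary GMT input that users can extend.

**ApopHigh classification.** A nucleus is ApopHigh when $T$ is at or above
the 90th percentile (linear-interpolation quantile between order statistics;
conventions differ, so this is pinned too) of the *pooled* score
distribution. Pooling is across conditions — a per-condition threshold would
make the resulting proportions incomparable, so it is deliberately not
offered. The default cell universe for both scoring and the threshold is
neurons, since priming of neurons is the question; `cell_mask` overrides
this. `PropHigh = ApopHigh / total` summaries are produced per condition,
per subtype × condition, and per donor × condition; donor-level proportions
feed a Kruskal–Wallis omnibus across the three conditions with pairwise
Wilcoxon rank-sum / Benjamini–Hochberg follow-ups, which respects donors,
not nuclei, as the replication unit.

## Nonparametric kernels

All testing uses the package's own kernels (`wilcoxon_rank_sum`,
`kruskal_wallis`, `benjamini_hochberg`): score distributions are skewed, so
rank-based tests are the right default. The rank-sum test enumerates the
complete permutation distribution when both groups have ≤ 10 observations
and no ties (two-sided $p = P(|W - EW| \ge |w - EW|)$), and otherwise uses
the normal approximation with tie-corrected variance and a continuity
correction; ties take mid-ranks everywhere. BH is the textbook step-up and
is applied within one analysis family at a time (one DE comparison, one
proportion-test run) — never globally across families. The base-R
implementations serve as independent cross-checks in the test suite, not as
the implementation, so the two routes stay distinct. Figure-legend sources
sometimes cite Dunn's post-hoc test for the three-group comparisons; the
methods-level description is pairwise Wilcoxon with BH, and that is what is
implemented.

## Cell-type proportion testing

`proportion_test` compares two conditions per cell type with a permutation
test: condition labels are shuffled over cells (totals fixed), the statistic
is $|\log_2 \text{FD}|$ with $\text{FD} = (p_b + \varepsilon)/(p_a +
\varepsilon)$ and the Haldane-style guard $\varepsilon = 1/(2\,\min(n_a,
n_b))$ so empty classes stay finite, and the add-one estimator $p = (1 +
\#\{|\text{perm}| \ge |\text{obs}|\})/(1 + n_\text{perm})$ never returns
exactly zero. A percentile bootstrap (resampling cells within condition)
gives the 95% interval; note a percentile interval is not mathematically
guaranteed to contain the observed statistic, so that property is checked
on typical data rather than enforced. Significance is the conjunction
`p_adj < 0.05` and `|log2FD| > 0.585`; 0.42 is exposed as the laxer variant
used for major-class panels. Cells, not donors, are the permutation unit —
this matches the design of the permutation proportion tests in common use
on single-cell data but ignores donor-level pseudo-replication; the
donor-resolved Kruskal–Wallis path above is the complementary, conservative
view, and both are reported by the pipeline.

The spatial arm of such studies compares neuron-type composition around
Nageotte nodules; only the downstream arithmetic is in scope here:
`nodule_adjacency_fold_change` computes mean within-sample proportions for
control / DPN nodule-adjacent / DPN non-adjacent neurons and their fold
changes with the same $\varepsilon$ guard.

## Differential expression

The published analyses use MAST per cell and DESeq2 on pseudobulk. Those
engines are not cloned here; the package provides two transparent stand-ins
with the same output schema (`gene, log2FC, p, p_adj, pct_a, pct_b, class`),
and downstream stages depend only on the schema:

* `de_rank_sum` — per-cell Wilcoxon rank-sum on log-normalized expression;
  `log2FC` is the ratio of group means of `expm1(lognorm)` with a 1e-9
  pseudocount; positive means higher in the second-named condition, and
  every table is labeled with its comparison to prevent sign drift.
* `de_pseudobulk_nb` — a minimal negative-binomial Wald test on pseudobulk
  sums: median-of-ratios size factors (geometric mean 1, library-size
  fallback when no gene is all-nonzero), per-gene method-of-moments
  dispersion shrunk toward the across-gene mean with weight $n/(n+4)$, and
  an expected-information IRLS fit of `log mu = offset + b0 + b1·condition`.

Gene-level results are engine-dependent; what the package promises is the
schema and the operating characteristics measured in the acceptance tests
(sensitivity ≥ 0.9 at planted log2FC = 1 with 200 cells/group; NB type-I
error within its nominal band on Poisson nulls). The significance rule is
`|log2FC| > log2(1.33) ≈ 0.411` and `FDR < 0.05`; the threshold's printed
form ("log 1.33") does not name its base, and log2 is the only choice
commensurate with an `avg_log2FC` axis, so that is the default, with 0.585
available where the stricter variant is wanted. Whether per-cell DE should
carry a donor covariate is ambiguous in the source description; the
stand-in engines do not include one, and donor-aware conclusions should use
the pseudobulk engine, which works at donor resolution by construction.

## Ligand–receptor interactome

`filter_interactions` emits one record per (pair, comparison) for the three
comparisons control→diabetic, diabetic→DPN, control→DPN, with per-criterion
flags: (C1) ligand DE among all DRG cells *or* receptor DE among neurons at
`p_adj < 0.05` in that comparison; (C2) ligand and receptor not
significantly DE in opposite directions in that comparison; (C3a) receptor
pseudobulk log-normalized expression ≥ 0.01 in ≥ 1 of the neuronal
populations; (C3b) receptor expressed in ≥ 5% of all neurons in some
condition; (C3c) ligand expressed in ≥ 0.1% of all DRG cells in some
condition. Emission is per comparison where C1 holds in that comparison —
the source counting ("interactions across the 2 comparisons" vs "unique
interactions") is reproduced structurally this way. The rank score is a
documented reconstruction from its three named ingredients, $s(g) =
|\log_2\text{FC}| \cdot (-\log_{10} \max(p_\text{adj}, 10^{-300})) \cdot
\text{pct}$ summed over ligand and receptor; it is strictly monotone in each
ingredient, lives in one pluggable function, and ties are broken
lexicographically. A pair's overall score is the max over its records and
the top-k export is unique by pair. The "best source cell type" annotation
is the argmax of mean log-normalized ligand expression over non-neuronal
major types — a presentation choice, not part of eligibility.

## The synthetic cohort

`generate_cohort` draws gene-wise negative-binomial counts with a shared
dispersion (default 0.5 — adequate for rank-based tests and one fewer knob
than gene-specific dispersions) over a condensed 2000-gene universe hosting
the five 20-gene modules, 13 mitochondrial genes and anonymous fillers.
Gene relative abundances are log-normal (σ = 1) with the mitochondrial
share pinned at 5%; per-cell depth is log-normal with median 12,000. These
two choices were set together so that a healthy nucleus detects ~1400–1600
of the 2000 genes — the condensed analogue of post-QC snRNA-seq reality, in
which essentially all healthy nuclei clear the >1000-detected-genes filter
— and were fixed before any downstream testing. Low-quality cells (2% by
default) get depth ÷ 10 and mitochondrial share 15%, so they fail both QC
criteria. Planted effects multiply NB means (`expression_shift`) or tilt
the class probabilities with renormalization (`proportion_shift`,
infeasible shifts rejected before sampling); the truth table records each
effect as realized. All sampling comes from one seeded stream in a fixed
documented order (gene abundances; then per condition/donor: major types,
subtypes, low-quality flags, depths, counts), trading partial-regeneration
convenience for strict reproducibility.

What the generator does **not** emulate: gene–gene correlation, batch
effects, donor-specific expression shifts, ambient RNA, doublets, or
spatial structure. Passing tests therefore demonstrate the *procedures* are
correct and well calibrated under the stated stochastic model, not that the
biological conclusions of any particular dataset are right.

## Nageotte stratification and the pipeline

Nageotte burden scores in [0, 5] are stratified Low (≤ 2), Moderate–High
(2–4) and High (≥ 4); the published bins overlap at 4, and the package
resolves the overlap High-wins because the contrast "moderate-to-high
(3–4), excluding high (4–5)" only makes sense if 4 belongs to High. The
boundary is a parameter (`high_cut`) for users who want the other reading.

`run_pipeline` chains simulate → QC → normalize → score → proportions → DE
→ interactome from one config (R list or YAML), writes every stage as TSV
plus a manifest with config hash, seed, package version and per-file
checksums, and is byte-identical under rerun with the same config. QC is
applied before any analysis; the source pipeline's ordering of QC versus
integration is not stated, and QC-first is the defensible default when no
integration step exists.

## Problem sizes and numerical choices

The acceptance suite runs the planted-apoptosis recovery on the full
default cohort (30 donors × 1000 cells × 2000 genes) for 10 seeds;
proportion-test calibration uses 500 annotation-only null cohorts (the test
consumes labels, so `n_genes` is held at the minimum the module layout
allows); DE recovery uses 200 cells per group over 2000 genes for 10 seeds;
the NB type-I run uses 200 rounds of 300 Poisson genes at 6 vs 6
replicates; interactome recovery uses 4000 cells per condition so that a
fibroblast-confined ligand induction is detectable as DE among all DRG
cells (a rank-sum test's power for a shift confined to ~10% of cells is
bounded by that mass fraction, so the cohort must be large enough for the
filter to see the signal). The reproducibility script
(`scripts/acceptance.R`) re-measures the same quantities at reduced seed
counts. Numerical guards: p_adj floored at 1e-300 in the interactome score;
NB dispersion floored at 1e-8; IRLS capped at 25 iterations with tolerance
1e-8; BH clips at 1; the permutation estimator adds one to numerator and
denominator.

## Known limitations

* The DE stand-ins are not MAST/DESeq2; gene-level outputs will differ from
  the published tools even on identical data.
* The cell-level permutation proportion test inherits the
  pseudo-replication caveat of its design; donor-level tests are the
  conservative companion.
* The interactome rank-score formula is a reconstruction; only its
  ingredients and monotonicity are anchored.
* Headline counts of the motivating study (nuclei retained, DE gene counts,
  1179/788 interaction counts) depend on access-controlled donor data and
  are not reproducible at desk scale; the package's claims are the
  calibrated operating characteristics above.
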