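---
title: "Methods: co-expression modules, consensus hubs and SVM-RFE biomarker selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-expression modules, consensus hubs and SVM-RFE biomarker selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexmark)
```

## The analysis

`coexmark` implements a whole-blood mRNA biomarker-discovery funnel for
ankylosing spondylitis (AS) versus healthy controls (HC):

1. **Preprocessing** — k-nearest-neighbor imputation of missing values,
   per-batch location adjustment, and a variance filter keeping the top
   25% most variable genes as the network universe.
2. **Weighted co-expression network** — Pearson correlations raised to a
   soft-threshold power β chosen by the scale-free topology criterion,
   topological overlap, average-linkage clustering into modules (minimum
   size 30), module eigengenes, and module-trait correlation with
   selection at |r| ≥ 0.3.
3. **Per-module gene-set enrichment** — pre-ranked weighted
   Kolmogorov–Smirnov enrichment with permutation p-values, reported at
   P < 0.05.
4. **Differential expression** — empirical-Bayes moderated t between the
   groups, Benjamini–Hochberg adjustment, and the filters adjusted
   p < 0.01 and |log2FC| > 1; the DE genes are intersected with the
   selected modules' genes to form the *feature genes*.
5. **Consensus hubs** — twelve node centralities on a protein-interaction
   graph over the feature genes; per measure the top 25% of nodes are
   listed, and a gene occurring in more than 4 of the 12 lists is a hub.
6. **SVM-RFE** — backward elimination ranked by squared linear-SVM
   weights, a stratified 5-fold cross-validated error curve over nested
   top-k feature sets, and the key genes at the curve minimum.
7. **Evaluation** — per-gene ROC AUC with Mann–Whitney significance
   (non-significant key genes are discarded), one-way ANOVA group tests,
   and Pearson correlation with a 0–10 disease-activity score (BASDAI
   style) among cases only, since controls carry no such score.

Every stage is an exported function; `run_pipeline()` chains them, and
the numbered scripts under `analysis/` run them file-to-file.

## The synthetic-data generator

Real whole-blood data for this design (52 AS / 20 HC) cannot certify an
implementation because the truth is unknown. The generator therefore
plants known structure:

$$x_{gs} = \mu_g + \lambda\, f_{m(g)}(s) + \delta\,
  \mathbf{1}[g \in D]\,\mathbf{1}[s \in \text{AS}] + b_{\text{batch}(s)}
  + \varepsilon_{gs},\qquad \varepsilon_{gs} \sim N(0, \sigma^2)$$

with one latent factor per module ($f_m \sim N(0,1)$ per sample), a
module-level trait link (the factor of trait-linked modules gains a mean
shift, default 1.0, in cases), a per-gene shift δ (default 1.5 on the
log2 scale) for the discriminative set $D$ (drawn from trait-linked
modules first, so module selection and DE filtering funnel toward the
same genes, as in the real analysis), uniform missingness, and additive
per-batch offsets. Defaults mirror the study scale: 2000 genes, four
modules of 100, λ = 0.8, σ = 1, 60 discriminative genes, 52 + 20
samples. Companion generators plant hubs in an Erdős–Rényi interaction
graph, build gene sets enriched for the planted signal, and produce a
severity score coupled to chosen driver genes, rescaled into [0, 10] and
defined for cases only.

What the generator does **not** emulate: probe-level microarray noise,
heavy-tailed and gene-specific variance profiles, correlated background
(beyond the planted modules), and annotation errors. Passing recovery
tests therefore certifies the *algorithms*, not performance on any real
cohort.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `powers`, `r2_cut` | 1–20, 0.9 | soft-threshold scan grid and the signed scale-free fit cut; the smallest adequate power is chosen |
| `min_module_size` | 30 genes | clusters below this become the grey (unassigned) bin |
| `merge_cut` | 0.25 | eigengene dissimilarity (1 − cor) below which modules merge |
| `trait_cutoff` | 0.3 | module-trait |r| selection cut |
| `de_p`, `de_lfc` | 0.01, 1 | BH-adjusted p and log2 fold-change cuts (strict inequalities) |
| `gsea_alpha` | 0.05 | nominal reporting cut; no cross-set FDR is computed |
| `hub_fraction`, `hub_min_count` | 0.25, 5 | top fraction per centrality and the "more than 4 of 12" occurrence rule |
| `rfe_folds`, `svm_cost` | 5, 1 | CV folds and the soft-margin cost |

The fold-change cut is interpreted on the log2 scale (|log2FC| > 1,
i.e. two-fold): a natural-scale cut of 1 excludes nothing.

## Numerical and design choices

* **Scale-free fit index.** R² of the log10-frequency versus
  log10-connectivity regression over ten equal-width bins, signed by the
  *negated* slope, so a decaying power law scores +1. Mean connectivity
  is reported but never used for selection.
* **Unsigned network.** Adjacency \(a_{ij} = |r_{ij}|^\beta\); the signed
  variant \(((1+r)/2)^\beta\) is available via `mode = "signed"`.
* **Adaptive tree cut.** Raising β compresses topological-overlap
  dissimilarities toward 1, so no fixed cut height separates modules
  across powers (at β ≈ 14–20 the informative merges happen between
  0.999 and 1.0). The default cut therefore scans the nested partitions
  `cutree(hc, k = 1..200)` and keeps the one with the most clusters of
  at least `min_size` genes, ties going to the coarsest partition; any
  oversplitting is undone by eigengene merging. A numeric `cut_height`
  restores the classical static cut. This replaces a dynamic-hybrid tree
  cut, which would be out of proportion here; planted-module recovery
  tests define correctness (adjusted Rand index ≥ 0.8, in practice ≈ 1.0
  at the default study conditions).
* **Eigengene sign.** The first right-singular vector of the
  gene-standardized module submatrix is flipped so its correlation with
  the module mean profile is non-negative; zero-variance genes are
  dropped with a warning.
* **Module preservation.** A permutation Z of mean intramodular
  adjacency (labels reassigned uniformly at random), not the full
  multi-statistic preservation suite: planted modules score Z ≫ 3,
  random subsets |Z| < 3.
* **Moderated t.** The variance prior (d₀, s₀²) is estimated by moment
  matching on log variances — `trigamma(d0/2) = var(log s²) −
  trigamma(d/2)` solved by bisection, with d₀ = ∞ (complete shrinkage)
  when observed spread does not exceed sampling noise. The statistics
  agree with `limma::eBayes` to machine precision on shared input;
  `d0_override = 0` recovers the ordinary two-sample t.
* **Batch adjustment** is per-gene location (batch means moved to the
  grand mean) rather than empirical-Bayes shrinkage of both moments: the
  generator's batch model is purely additive, so location adjustment
  removes it exactly (post-adjustment batch F-statistics collapse to 0).
* **GSEA.** Weight p = 1 (classic; p = 0 gives the analytic KS case).
  The signal-to-noise denominator floors each group sd at 0.2·|mean|
  (0.2 if the mean is 0). Permutation p-values use the add-one rule so
  they are never 0; phenotype permutation requires ≥ 7 samples per
  group, otherwise gene-set permutation is used with a warning. No NES
  or cross-set FDR: the workflow filters on nominal P < 0.05 only.
* **Centralities.** Closeness is harmonic and eccentricity reciprocal so
  larger is always more central and disconnected graphs need no special
  casing; radiality follows the (Δ + 1 − d) form per component; MCC sums
  (|C|−1)! over maximal cliques; DMNC uses the published 1.7 exponent;
  BottleNeck's shortest-path tree is made deterministic by a
  smallest-node-id parent rule (this makes it, by construction, the one
  measure that is not invariant to relabeling when parents tie); EPC
  keeps each edge with probability 0.5 over seeded Monte-Carlo trials.
  All eleven deterministic measures match independent brute-force
  enumeration on every non-isomorphic graph with ≤ 6 nodes.
* **SVM-RFE.** The ranking uses a linear kernel because the weight
  vector is only defined for linear decision functions, even though a
  radial kernel is offered for the CV-curve classifier; elimination is
  one feature per iteration with ties removing the higher feature index
  first; standardization is computed inside training folds only. The CV
  curve evaluates the *full-data* ranking (as the original workflow
  does), which optimistically biases the error curve — a known property
  of this design, visible in the recovery experiments: at effect 1.5 and
  n = 36 the curve bottoms out at k* ≈ 3–8, so the selected set cannot
  contain most of 8 planted features, and measured key-gene recall is
  ≈ 0.5. We report this honestly rather than re-ranking inside folds,
  which would be a different (better) method than the one reimplemented.
* **AUC.** Mann–Whitney U with ties counted ½; significance from the
  tie-corrected normal approximation.
* **DE recovery scoring.** Recall is measured against the planted
  per-gene-shift set; a *false* discovery is a gene with no planted
  group effect at all — genes of trait-linked modules carry a real
  factor-mediated shift (λ × factor shift ≈ 0.8) and are excluded from
  the null set.

## Problem sizes used in tests and the acceptance script

Recovery and calibration experiments run at 200–2000 genes, 20–72
samples, 5–20 seeds, 500 permutations, and 63-feature RFE problems; the
full synthetic pipeline runs at the study scale (2000 × 72) in a few
seconds. These sizes were chosen to make every planted effect detectable
at the stated effect sizes while keeping the whole suite quick to re-run.

## Known limitations

* Single-dataset module detection only: no multi-set consensus modules
  and no block-wise decomposition for very large gene universes.
* Two-group designs without covariates; severity correlation is
  cases-only Pearson.
* The interaction graph is consumed as an edge list (or generated); no
  live database queries.
* Real-accession behavior (e.g. the published choice of β = 14 on
  GSE73754) can be reproduced with `analysis/09_real_data.R` given a
  locally downloaded series matrix, but is not certified by this
  package's tests.
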