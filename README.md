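# coexmark

Whole-blood transcriptome biomarker discovery for ankylosing spondylitis
(AS) versus healthy controls (HC), packaged as a tested, reusable R
pipeline. It reimplements the full funnel used by WGCNA-plus-machine-
learning biomarker studies:

1. **Preprocess** — KNN imputation, per-batch location adjustment, top-25%
   variance filter.
2. **Co-expression network** — soft-threshold power β chosen as the
   smallest power with signed scale-free fit R² ≥ 0.9 (adjacency
   a_ij = |cor(x_i, x_j)|^β), topological overlap
   TOM_ij = (ℓ_ij + a_ij) / (min(k_i, k_j) + 1 − a_ij), average-linkage
   module detection (minimum size 30) with eigengene merging, and
   module-trait selection at |r| ≥ 0.3.
3. **Per-module GSEA** — weighted Kolmogorov–Smirnov enrichment score with
   permutation p-values, reported at P < 0.05.
4. **Differential expression** — empirical-Bayes moderated t
   (t̃_g = log2FC / (s̃_g √(1/n₁ + 1/n₂)), s̃²_g = (d₀s₀² + d_g s²_g)/(d₀ + d_g)),
   BH-adjusted p < 0.01 and |log2FC| > 1, intersected with the selected
   modules' genes.
5. **Consensus hubs** — twelve node centralities (Degree, Betweenness,
   harmonic Closeness, Eccentricity, Radiality, Stress, Clustering
   Coefficient, MNC, DMNC, MCC, BottleNeck, EPC) on a protein-interaction
   graph; hubs = genes in the top 25% of more than 4 of the 12 rankings.
6. **SVM-RFE** — backward elimination ranked by squared linear-SVM weights
   w_i², with a stratified 5-fold cross-validated error curve choosing the
   key-gene count k*.
7. **Evaluate** — per-gene ROC AUC (Mann–Whitney) screening, one-way
   ANOVA, and Pearson correlation with a 0–10 disease-activity (BASDAI
   style) score among cases.

A synthetic-data module plants known co-expression modules, discriminative
genes, network hubs, enriched gene sets and a severity score, so every
stage is scored against ground truth (adjusted Rand index, precision /
recall, calibration). See `vignettes/methods.Rmd` for the model, the
defaults and the design choices.

## Worked example

The numbered drivers under `analysis/` run the funnel file-to-file on a
simulated 52 AS / 20 HC study (2000 genes, four planted modules of 100,
60 discriminative genes, 1% missing cells):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_preprocess.R
Rscript analysis/03_network_modules.R
# ... through analysis/08_evaluate.R
```

which prints, stage by stage:

```
simulated 2000 genes x 72 samples (52 cases, 20 controls)
imputed 1474 missing cells; kept 500 / 2000 genes (top 25% variance)
chosen power beta = 17 (signed R^2 = 0.863)
modules selected at |r| >= 0.3: turquoise
differential expression: 71 up, 0 down
feature genes (selected modules turquoise ∩ DE): 70
consensus hubs (>4 of 12 lists): 18; planted hubs recovered: 6/6
CV error minimum at k* = 10 features (CV accuracy 98.7%, training accuracy 98.6%)
ROC screening: 10/10 key genes significant (discarded: none)
5 key genes significantly correlated with severity
recovery: module ARI 1.000 | DE recall 1.00 (null-FDP 0.014) | hub recall 1.00 | key-gene precision 0.80
```

Reading the funnel: the four planted modules are recovered exactly (ARI
1.0) and the trait-linked module ("turquoise", module-trait r = 0.72) is
the only one passing the 0.3 cut; its genes intersected with the 71
differentially expressed genes give 70 feature genes; the consensus rule
finds 18 hubs including all 6 planted ones; cross-validation selects 10
key genes (8 of them planted discriminative genes), all significant by
ROC, 5 of them correlated with the severity score. On this run no power
reached the 0.9 scale-free cut, so the scan fell back (with a warning) to
the best-fitting power, 17 — the fallback the selection rule prescribes.
All outputs land in `results/` as TSV/JSON.

`analysis/09_real_data.R` applies the same soft-threshold scan to a
locally downloaded GEO series matrix (the study accession is GSE73754);
nothing is downloaded by this repository.

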