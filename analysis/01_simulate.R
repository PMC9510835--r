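#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study --------------------------------
# A whole-blood-like case/control expression study (52 AS / 20 HC, 2000
# genes, four planted co-expression modules of 100 genes, 60
# discriminative genes, unit noise) plus gene sets and a severity score,
# written as plain-text artifacts for the downstream stages.

suppressMessages(library(coexmark))
dir.create("results", showWarnings = FALSE)

seed <- 42
cfg <- synthetic_config(missing_rate = 0.01, seed = seed)
sim <- generate_expression(cfg)
sets <- generate_gene_sets(sim$truth, n_enriched = 5, n_null = 20,
                           set_size = 40, seed = seed + 1)
sim$phenotypes$severity <- generate_severity(
  sim$phenotypes, sim$expression,
  head(sim$truth$discriminative_genes, 5), coupling = 2, seed = seed + 2)

write_expression_tsv(sim$expression, "results/expression.tsv")
write_phenotypes_csv(sim$phenotypes, "results/phenotypes.csv")
write_gmt(sets, "results/gene_sets.gmt")
write_ground_truth(sim$truth, "results/ground_truth.json")

cat(sprintf("simulated %d genes x %d samples (%d cases, %d controls)\n",
            nrow(sim$expression), ncol(sim$expression),
            cfg$n_samples_case, cfg$n_samples_control))
cat(sprintf("planted: %d modules, %d discriminative genes, %d missing cells\n",
            cfg$n_modules, length(sim$truth$discriminative_genes),
            sum(is.na(sim$expression))))
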