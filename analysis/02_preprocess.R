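#!/usr/bin/env Rscript
# Stage 2: impute, batch-adjust, variance-filter ------------------------
# KNN imputation of missing cells, per-batch location adjustment (no-op
# for the single-batch simulation), and the top-25% variance filter that
# defines the co-expression network's gene universe.

suppressMessages(library(coexmark))

expr <- read_expression_tsv("results/expression.tsv")
phen <- read_phenotypes_csv("results/phenotypes.csv")

imputed <- knn_impute(expr, k = 10)
if (!is.null(phen$batch) && length(unique(phen$batch)) > 1) {
  imputed <- adjust_batches(imputed, phen)
}
write_expression_tsv(imputed, "results/expression_imputed.tsv")

filtered <- variance_filter(imputed, 0.25)
write_expression_tsv(filtered, "results/expression_network.tsv")

cat(sprintf("imputed %d missing cells; kept %d / %d genes (top 25%% variance)\n",
            sum(is.na(expr)), nrow(filtered), nrow(expr)))
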