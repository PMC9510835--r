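#!/usr/bin/env Rscript
# Stage 7: SVM-RFE over the hub genes -------------------------------------
# Backward elimination ranked by squared linear-SVM weights, a 5-fold
# cross-validated error curve over nested top-k feature sets, and the
# key-gene set at the curve's minimum.

suppressMessages(library(coexmark))

mat <- read_expression_tsv("results/expression_imputed.tsv")
phen <- read_phenotypes_csv("results/phenotypes.csv")
hubs <- readLines("results/hub_genes.txt")

X <- t(mat[hubs, , drop = FALSE])
y <- phen$group[match(rownames(X), phen$sample_id)]

rfe <- rfe_rank(X, y, step = 1, C = 1, seed = 7)
write.table(data.frame(feature = names(rfe$ranking), rank = rfe$ranking),
            "results/rfe_ranking.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cvc <- cv_error_curve(X, y, rfe$ranking, n_folds = 5, seed = 8)
write.table(cvc$curve, "results/cv_error_curve.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

sel <- select_key_features(X, y, cvc, rfe$ranking)
writeLines(sel$key_features, "results/key_genes.txt")
cat(sprintf("CV error minimum at k* = %d features (CV accuracy %.1f%%, training accuracy %.1f%%)\n",
            sel$k_star, 100 * sel$cv_accuracy, 100 * sel$training_accuracy))
cat("key genes:", paste(sel$key_features, collapse = ", "), "\n")
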