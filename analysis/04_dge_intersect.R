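#!/usr/bin/env Rscript
# Stage 4: differential expression and the module/DE intersection -------
# Empirical-Bayes moderated t between AS and HC on the full imputed
# matrix, BH adjustment, the adjusted-p < 0.01 and |log2FC| > 1 filters,
# then intersection with the trait-selected modules' genes to form the
# feature-gene set.

suppressMessages(library(coexmark))

mat <- read_expression_tsv("results/expression_imputed.tsv")
phen <- read_phenotypes_csv("results/phenotypes.csv")
labels_df <- read.delim("results/module_assignment.tsv")
labels <- setNames(labels_df$module, labels_df$gene)
mt <- read.delim("results/module_trait.tsv")

tab <- moderated_t_test(mat, phen)
write.table(tab, "results/dge_table.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
de <- filter_de(tab, p_cut = 0.01, lfc_cut = 1)
cat(sprintf("differential expression: %d up, %d down\n",
            length(de$up), length(de$down)))

selected <- mt$module[mt$selected]
features <- intersect_with_modules(c(de$up, de$down), labels, selected)
writeLines(features, "results/feature_genes.txt")
cat(sprintf("feature genes (selected modules %s ∩ DE): %d\n",
            paste(selected, collapse = "/"), length(features)))
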