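#!/usr/bin/env Rscript
# Stage 3: co-expression network and modules ----------------------------
# Soft-threshold scan (smallest power with scale-free fit >= 0.9),
# adjacency and topological overlap, module detection with eigengene
# merging, module-trait correlation at the |r| >= 0.3 cut, gene
# significance / module membership, and a permutation preservation Z.

suppressMessages(library(coexmark))

mat <- read_expression_tsv("results/expression_network.tsv")
phen <- read_phenotypes_csv("results/phenotypes.csv")

st <- pick_soft_threshold(mat)
write.table(st$scan, "results/soft_threshold_scan.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("chosen power beta = %d (signed R^2 = %.3f)\n", st$beta,
            st$scan$r_squared[st$scan$power == st$beta]))

adj <- adjacency_from_cor(cor(t(mat)), st$beta)
tom <- tom_similarity(adj)
mod <- detect_modules(tom, mat, min_size = 30)
cat("module sizes:\n"); print(mod$sizes)
write.table(data.frame(gene = names(mod$labels), module = mod$labels),
            "results/module_assignment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

mt <- module_trait_correlation(mod$eigengenes, phen, cutoff = 0.3)
write.table(mt, "results/module_trait.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("modules selected at |r| >= 0.3:",
    paste(mt$module[mt$selected], collapse = ", "), "\n")

gts <- gene_trait_stats(mat, mod$eigengenes, phen, mod$labels)
write.table(gts$module_summary, "results/mm_vs_gs.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

z <- preservation_z(mat, mod$labels, n_permutations = 100, seed = 1,
                    beta = st$beta)
write.table(data.frame(module = names(z), preservation_z = z),
            "results/preservation_z.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("preservation Z:\n"); print(round(z, 1))
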