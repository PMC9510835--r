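#!/usr/bin/env Rscript
# Stage 6: interaction network and consensus hubs ------------------------
# An interaction graph over the feature genes (here generated with
# planted hubs recorded in the ground truth; a STRING-style edge list can
# be substituted), the twelve centrality scores, and the consensus rule:
# top 25% per measure, hub if present in more than 4 of the 12 lists.

suppressMessages(library(coexmark))

features <- readLines("results/feature_genes.txt")
truth <- read_ground_truth("results/ground_truth.json")

set.seed(5)
planted <- generate_ppi_graph(
  n_nodes = length(features),
  n_hubs = max(2L, round(0.08 * length(features))),
  hub_degree_boost = max(6L, round(0.25 * length(features))),
  edge_prob = 0.05, seed = 5, node_ids = features)
g <- planted$graph
el <- igraph::as_data_frame(g)
names(el) <- c("node_a", "node_b")
write_edge_list(el, "results/ppi_edges.tsv")
writeLines(planted$truth$planted_hubs, "results/planted_hubs.txt")
cat(sprintf("interaction graph: %d nodes, %d edges, %d planted hubs\n",
            igraph::vcount(g), igraph::ecount(g),
            length(planted$truth$planted_hubs)))

cent <- compute_centralities(g, epc_trials = 1000, seed = 6)
write.table(cbind(node = rownames(cent), cent), "results/centralities.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

hubsel <- consensus_hubs(cent, fraction = 0.25, min_count = 5)
write.table(data.frame(node = names(hubsel$occurrence),
                       occurrence = hubsel$occurrence),
            "results/hub_occurrence.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
writeLines(hubsel$hubs, "results/hub_genes.txt")
cat(sprintf("consensus hubs (>4 of 12 lists): %d; planted hubs recovered: %d/%d\n",
            length(hubsel$hubs),
            length(intersect(hubsel$hubs, planted$truth$planted_hubs)),
            length(planted$truth$planted_hubs)))
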