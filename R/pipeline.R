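#' Default stage parameters for the end-to-end run
#'
#' Thresholds mirror the published workflow: soft-threshold scan over
#' powers 1-20 with a 0.9 scale-free fit cut, minimum module size 30,
#' module-trait selection at |r| >= 0.3, DE cuts adjusted p < 0.01 and
#' |log2FC| > 1, per-module enrichment reported at p < 0.05, hub consensus
#' over the top 25% of each of the 12 centrality rankings with hubs at
#' occurrence >= 5, a 5-fold CV error curve for the feature elimination,
#' and ROC screening at alpha 0.05.
#'
#' @return Named list of parameters.
#' @export
default_params <- function() {
  list(powers = 1:20, r2_cut = 0.9,
       knn_k = 10, variance_top = 0.25,
       min_module_size = 30, cut_height = NULL, merge_cut = 0.25,
       trait_cutoff = 0.3,
       de_p = 0.01, de_lfc = 1,
       gsea_n_perm = 200, gsea_mode = "gene_set", gsea_alpha = 0.05,
       gsea_top_n = 10,
       hub_fraction = 0.25, hub_min_count = 5, epc_trials = 200,
       rfe_folds = 5, rfe_step = 1, svm_cost = 1,
       roc_alpha = 0.05)
}

.stage_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 97 + k * 1009) %% 2147483629)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the whole biomarker-discovery pipeline
#'
#' Stages: preprocess (impute, optional batch adjustment, variance filter)
#' -> co-expression network and modules -> module-trait selection ->
#' per-module enrichment -> moderated-t differential expression ->
#' module/DE intersection -> interaction-network consensus hubs -> SVM-RFE
#' with CV curve -> ROC screening and severity correlation. Every
#' intermediate table is written to `outdir`; the returned report carries
#' the funnel counts. Empty intermediate sets downgrade later stages to
#' no-ops with warnings rather than failing.
#'
#' For synthetic runs (`config$synthetic` is a [synthetic_config()]) the
#' generator also produces gene sets, a severity score and a planted-hub
#' interaction graph over the feature genes, and the report includes
#' ground-truth recovery metrics.
#'
#' @param config list with elements: either `synthetic` (a
#'   [synthetic_config()]) or `expression` + `phenotypes` (matrices/data
#'   frames or file paths), optional `gene_sets` (list or GMT path),
#'   optional `edge_list` (data.frame or TSV path) with optional
#'   `edge_score_min`, `outdir`, `seed`, and optional `params` overriding
#'   [default_params()] entries.
#' @return Report list (also written to `outdir/report.json`).
#' @export
run_pipeline <- function(config) {
  params <- utils::modifyList(default_params(), config$params %||% list())
  seed <- config$seed %||% 1L
  outdir <- config$outdir %||% tempfile("coexmark_run_")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = seed, params = params, counts = list(), notes = list())

  ## ---- inputs -------------------------------------------------------
  truth <- NULL
  sets <- NULL
  if (!is.null(config$synthetic)) {
    sim <- generate_expression(config$synthetic)
    expr <- sim$expression
    phen <- sim$phenotypes
    truth <- sim$truth
    sets <- generate_gene_sets(truth, n_enriched = 5, n_null = 20,
                               set_size = 40, seed = .stage_seed(seed, 1))
    drivers <- utils::head(truth$discriminative_genes, 5)
    if (length(drivers)) {
      phen$severity <- generate_severity(phen, expr, drivers, coupling = 2,
                                         seed = .stage_seed(seed, 2))
    }
    write_expression_tsv(expr, file.path(outdir, "expression.tsv"))
    write_phenotypes_csv(phen, file.path(outdir, "phenotypes.csv"))
    write_gmt(sets, file.path(outdir, "gene_sets.gmt"))
    write_ground_truth(truth, file.path(outdir, "ground_truth.json"))
  } else {
    expr <- config$expression
    if (is.character(expr)) expr <- read_expression_tsv(expr)
    phen <- config$phenotypes
    if (is.character(phen)) phen <- read_phenotypes_csv(phen)
    if (!is.null(config$gene_sets)) {
      sets <- config$gene_sets
      if (is.character(sets)) sets <- read_gmt(sets)
    }
  }

  ## ---- preprocess ---------------------------------------------------
  n_missing <- sum(is.na(expr))
  imputed <- knn_impute(expr, k = params$knn_k)
  if (!is.null(phen$batch) && length(unique(phen$batch)) > 1L) {
    imputed <- adjust_batches(imputed, phen)
    report$counts$batch_adjusted <- TRUE
  }
  filtered <- variance_filter(imputed, params$variance_top)
  report$counts$n_imputed_cells <- n_missing
  report$counts$n_genes_total <- nrow(expr)
  report$counts$n_genes_network <- nrow(filtered)

  ## ---- co-expression network and modules ----------------------------
  st <- pick_soft_threshold(filtered, powers = params$powers,
                            r2_cut = params$r2_cut)
  .write_tsv(st$scan, file.path(outdir, "soft_threshold_scan.tsv"))
  report$counts$beta <- st$beta
  cm <- stats::cor(t(filtered))
  adj <- adjacency_from_cor(cm, st$beta)
  tom <- tom_similarity(adj)
  mod <- detect_modules(tom, filtered, min_size = params$min_module_size,
                        cut_height = params$cut_height,
                        merge_cut = params$merge_cut)
  .write_tsv(data.frame(gene = names(mod$labels), module = mod$labels),
             file.path(outdir, "module_assignment.tsv"))
  report$counts$n_modules <- length(mod$sizes)
  report$counts$module_sizes <- as.list(mod$sizes)

  if (is.null(mod$eigengenes)) {
    warning("no modules detected: downstream stages skipped")
    report$notes$halted_at <- "module_detection"
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(report)
  }

  mt <- module_trait_correlation(mod$eigengenes, phen,
                                 cutoff = params$trait_cutoff)
  .write_tsv(mt, file.path(outdir, "module_trait.tsv"))
  selected <- mt$module[mt$selected]
  report$counts$selected_modules <- selected
  gts <- gene_trait_stats(filtered, mod$eigengenes, phen, mod$labels)
  if (!is.null(gts$module_summary)) {
    .write_tsv(gts$module_summary, file.path(outdir, "mm_vs_gs.tsv"))
  }

  ## ---- per-module enrichment ---------------------------------------
  if (!is.null(sets) && length(selected)) {
    gsea_all <- do.call(rbind, lapply(selected, function(m) {
      res <- gsea_per_module(filtered, phen, mod$labels, m, sets,
                             n_perm = params$gsea_n_perm,
                             mode = params$gsea_mode,
                             seed = .stage_seed(seed, 3),
                             top_n = params$gsea_top_n)
      if (nrow(res)) cbind(module = m, res) else NULL
    }))
    if (!is.null(gsea_all)) {
      .write_tsv(gsea_all, file.path(outdir, "gsea_per_module.tsv"))
      report$counts$n_enriched_sets <-
        sum(gsea_all$p_value < params$gsea_alpha)
    }
  }

  ## ---- differential expression --------------------------------------
  de_tab <- moderated_t_test(imputed, phen)
  .write_tsv(de_tab, file.path(outdir, "dge_table.tsv"))
  de <- filter_de(de_tab, p_cut = params$de_p, lfc_cut = params$de_lfc)
  de_genes <- c(de$up, de$down)
  report$counts$n_de_up <- length(de$up)
  report$counts$n_de_down <- length(de$down)

  feature_genes <- if (length(selected) && length(de_genes)) {
    suppressWarnings(intersect_with_modules(de_genes, mod$labels, selected))
  } else character(0)
  report$counts$n_feature_genes <- length(feature_genes)
  writeLines(feature_genes, file.path(outdir, "feature_genes.txt"))

  finish <- function(report, note) {
    warning(note)
    report$notes$halted_at <- note
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    report
  }
  if (length(feature_genes) < 3L) {
    return(finish(report, "fewer than 3 feature genes after intersection"))
  }

  ## ---- interaction network and consensus hubs -----------------------
  if (!is.null(config$edge_list)) {
    edges <- config$edge_list
    if (is.character(edges)) {
      edges <- read_edge_list(edges, config$edge_score_min %||% 0)
    }
    edges <- edges[edges$node_a %in% feature_genes &
                     edges$node_b %in% feature_genes, , drop = FALSE]
    graph <- graph_from_edges(edges, nodes = feature_genes)
  } else if (!is.null(truth)) {
    planted <- generate_ppi_graph(
      n_nodes = length(feature_genes),
      n_hubs = max(2L, round(0.08 * length(feature_genes))),
      hub_degree_boost = max(6L, round(0.25 * length(feature_genes))),
      edge_prob = 0.05, seed = .stage_seed(seed, 4),
      node_ids = feature_genes)
    graph <- planted$graph
    truth$planted_hubs <- planted$truth$planted_hubs
  } else {
    return(finish(report, "no edge list supplied for the hub stage"))
  }
  report$counts$n_network_nodes <- igraph::vcount(graph)
  report$counts$n_network_edges <- igraph::ecount(graph)

  cent <- compute_centralities(graph, epc_trials = params$epc_trials,
                               seed = .stage_seed(seed, 5))
  .write_tsv(cbind(node = rownames(cent), cent),
             file.path(outdir, "centralities.tsv"))
  hubsel <- consensus_hubs(cent, fraction = params$hub_fraction,
                           min_count = params$hub_min_count)
  .write_tsv(data.frame(node = names(hubsel$occurrence),
                        occurrence = hubsel$occurrence),
             file.path(outdir, "hub_occurrence.tsv"))
  hubs <- hubsel$hubs
  report$counts$n_hubs <- length(hubs)
  if (length(hubs) < 2L) {
    return(finish(report, "fewer than 2 consensus hubs"))
  }

  ## ---- SVM-RFE -------------------------------------------------------
  X <- t(imputed[hubs, , drop = FALSE])
  y <- phen$group[match(rownames(X), phen$sample_id)]
  rfe <- rfe_rank(X, y, step = params$rfe_step, C = params$svm_cost,
                  seed = .stage_seed(seed, 6))
  cvc <- cv_error_curve(X, y, rfe$ranking, n_folds = params$rfe_folds,
                        C = params$svm_cost, seed = .stage_seed(seed, 7))
  .write_tsv(cvc$curve, file.path(outdir, "cv_error_curve.tsv"))
  sel <- select_key_features(X, y, cvc, rfe$ranking, C = params$svm_cost)
  report$counts$k_star <- sel$k_star
  report$counts$cv_accuracy <- sel$cv_accuracy
  report$counts$training_accuracy <- sel$training_accuracy
  report$counts$n_key_genes <- length(sel$key_features)
  writeLines(sel$key_features, file.path(outdir, "key_genes.txt"))

  ## ---- evaluation ----------------------------------------------------
  roc <- roc_screen(imputed, phen, genes = sel$key_features)
  roc$significant <- roc$p < params$roc_alpha
  .write_tsv(roc, file.path(outdir, "roc_table.tsv"))
  scr <- screen_significant(roc, alpha = params$roc_alpha)
  report$counts$n_key_significant <- length(scr$retained)
  report$counts$discarded_by_roc <- scr$discarded

  if (!is.null(phen$severity) && length(scr$retained)) {
    sev <- severity_correlation(imputed, phen, genes = scr$retained)
    .write_tsv(sev, file.path(outdir, "severity_correlation.tsv"))
    report$counts$n_severity_correlated <- sum(sev$significant)
  }

  if (!is.null(truth)) {
    rec <- recovery_metrics(truth,
                            module_labels = mod$labels,
                            de_genes = de_genes,
                            hubs = hubs,
                            key_genes = sel$key_features)
    report$recovery <- rec
  }

  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a
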