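#' Configuration for the synthetic expression generator
#'
#' The generator emulates the statistical structure a weighted
#' co-expression biomarker analysis assumes: a log2-scale gene x sample
#' matrix with a small number of planted modules (one latent factor per
#' module), a subset of discriminative genes carrying a case/control mean
#' shift, background noise genes, and optional missingness and additive
#' batch offsets. Defaults mirror a whole-blood case/control study of 52
#' cases and 20 controls.
#'
#' @param n_genes Total genes.
#' @param n_samples_case,n_samples_control Group sizes.
#' @param n_modules Number of planted co-expression modules.
#' @param module_sizes Integer vector of length `n_modules`; their sum must
#'   not exceed `n_genes` (the remainder are background genes).
#' @param factor_loading Loading of module genes on their latent factor.
#' @param trait_modules Indices of modules whose latent factor carries a
#'   case-group mean shift of `factor_shift` (module-level trait linkage).
#' @param factor_shift Case-group mean shift of trait-linked factors.
#' @param trait_effect Per-gene log2 mean shift for discriminative genes.
#' @param n_discriminative Number of genes given the per-gene shift; drawn
#'   first from trait-linked modules, then from background.
#' @param noise_sd Residual noise standard deviation (> 0).
#' @param missing_rate Fraction of cells masked missing, in [0, 1).
#' @param n_batches Number of batches (1 = no batch structure).
#' @param batch_sd Standard deviation of per-batch additive offsets.
#' @param seed Integer seed; the whole output is reproducible from it.
#' @return List of class "synthetic_config".
#' @export
synthetic_config <- function(n_genes = 2000,
                             n_samples_case = 52, n_samples_control = 20,
                             n_modules = 4, module_sizes = rep(100L, n_modules),
                             factor_loading = 0.8,
                             trait_modules = if (n_modules > 0) 1L else integer(0),
                             factor_shift = 1.0,
                             trait_effect = 1.5, n_discriminative = 60,
                             noise_sd = 1, missing_rate = 0,
                             n_batches = 1L, batch_sd = 0, seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_samples_case = as.integer(n_samples_case),
              n_samples_control = as.integer(n_samples_control),
              n_modules = as.integer(n_modules),
              module_sizes = as.integer(module_sizes),
              factor_loading = factor_loading,
              trait_modules = as.integer(trait_modules),
              factor_shift = factor_shift,
              trait_effect = trait_effect,
              n_discriminative = as.integer(n_discriminative),
              noise_sd = noise_sd, missing_rate = missing_rate,
              n_batches = as.integer(n_batches), batch_sd = batch_sd,
              seed = as.integer(seed))
  if (length(cfg$module_sizes) != cfg$n_modules) {
    stop("module_sizes must have length n_modules")
  }
  if (sum(cfg$module_sizes) > cfg$n_genes) {
    stop("sum(module_sizes) exceeds n_genes")
  }
  if (cfg$noise_sd <= 0) stop("noise_sd must be > 0")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    stop("missing_rate must be in [0, 1)")
  }
  if (cfg$n_discriminative > cfg$n_genes) {
    stop("n_discriminative exceeds n_genes")
  }
  if (length(cfg$trait_modules) && any(cfg$trait_modules > cfg$n_modules)) {
    stop("trait_modules out of range")
  }
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate a synthetic expression study with known ground truth
#'
#' Model: x[g,s] = mu_g + lambda * f_m(s) (module genes)
#' + delta * 1(g discriminative) * 1(s case) + b(batch(s)) + eps,
#' with f_m ~ N(0,1) per sample (plus `factor_shift` for cases in
#' trait-linked modules) and eps ~ N(0, noise_sd^2). Missing cells are
#' masked uniformly at random at `missing_rate`.
#'
#' @param config A [synthetic_config()].
#' @return list(expression, phenotypes, truth) where truth records module
#'   labels per gene ("background" for non-module genes), the
#'   discriminative gene set, trait-linked module ids, and the config.
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n_s <- config$n_samples_case + config$n_samples_control
  gene_ids <- sprintf("G%04d", seq_len(config$n_genes))
  sample_ids <- sprintf("S%03d", seq_len(n_s))
  is_case <- c(rep(1, config$n_samples_case), rep(0, config$n_samples_control))

  module_of <- rep("background", config$n_genes)
  idx <- 1L
  for (m in seq_len(config$n_modules)) {
    module_of[idx:(idx + config$module_sizes[m] - 1L)] <- paste0("M", m)
    idx <- idx + config$module_sizes[m]
  }

  trait_mods <- paste0("M", config$trait_modules)
  pool <- which(module_of %in% trait_mods)
  n_disc <- config$n_discriminative
  disc <- integer(0)
  if (n_disc > 0) {
    take <- min(n_disc, length(pool))
    disc <- if (take > 0) sample(pool, take) else integer(0)
    if (n_disc > take) {
      bg <- which(module_of == "background")
      disc <- c(disc, sample(bg, n_disc - take))
    }
  }

  mu <- stats::rnorm(config$n_genes, mean = 7, sd = 0.5)
  X <- matrix(mu, nrow = config$n_genes, ncol = n_s)
  factors <- matrix(stats::rnorm(config$n_modules * n_s), config$n_modules, n_s)
  for (m in config$trait_modules) {
    factors[m, ] <- factors[m, ] + config$factor_shift * is_case
  }
  for (m in seq_len(config$n_modules)) {
    rows <- module_of == paste0("M", m)
    X[rows, ] <- X[rows, ] +
      config$factor_loading * matrix(factors[m, ], sum(rows), n_s, byrow = TRUE)
  }
  if (length(disc)) {
    X[disc, is_case == 1] <- X[disc, is_case == 1] + config$trait_effect
  }

  batch <- rep_len(paste0("B", seq_len(config$n_batches)), n_s)
  if (config$n_batches > 1L && config$batch_sd > 0) {
    offs <- stats::rnorm(config$n_batches, sd = config$batch_sd)
    X <- X + matrix(offs[match(batch, paste0("B", seq_len(config$n_batches)))],
                    config$n_genes, n_s, byrow = TRUE)
  }
  X <- X + matrix(stats::rnorm(length(X), sd = config$noise_sd),
                  config$n_genes, n_s)
  if (config$missing_rate > 0) {
    mask <- stats::runif(length(X)) < config$missing_rate
    X[mask] <- NA_real_
  }
  dimnames(X) <- list(gene_ids, sample_ids)

  phenotypes <- data.frame(
    sample_id = sample_ids,
    group = ifelse(is_case == 1, "AS", "HC"),
    batch = batch,
    stringsAsFactors = FALSE)

  truth <- list(
    module_label_per_gene = stats::setNames(module_of, gene_ids),
    discriminative_genes = gene_ids[sort(disc)],
    trait_linked_modules = trait_mods,
    planted_hubs = character(0),
    generating_config = config)

  list(expression = X, phenotypes = phenotypes, truth = truth)
}

#' Generate an interaction graph with planted hubs
#'
#' Erdos-Renyi background at `edge_prob` plus, for each planted hub,
#' `hub_degree_boost` extra edges to uniformly chosen current non-neighbors.
#'
#' @param n_nodes,n_hubs Node and hub counts (n_hubs < n_nodes).
#' @param hub_degree_boost Extra edges attached to each hub.
#' @param edge_prob Background edge probability.
#' @param seed Integer seed.
#' @param node_ids Optional node names (default N001...).
#' @return list(graph = igraph, truth = list(planted_hubs = ...)).
#' @export
generate_ppi_graph <- function(n_nodes, n_hubs, hub_degree_boost,
                               edge_prob, seed, node_ids = NULL) {
  if (n_hubs >= n_nodes) stop("n_hubs must be < n_nodes")
  set.seed(seed)
  if (is.null(node_ids)) node_ids <- sprintf("N%03d", seq_len(n_nodes))
  stopifnot(length(node_ids) == n_nodes)
  adj <- matrix(FALSE, n_nodes, n_nodes)
  if (edge_prob > 0) {
    up <- which(upper.tri(adj))
    adj[up] <- stats::runif(length(up)) < edge_prob
    adj <- adj | t(adj)
  }
  hubs <- sample.int(n_nodes, n_hubs)
  for (h in hubs) {
    cand <- setdiff(which(!adj[h, ]), h)
    if (length(cand) < hub_degree_boost) {
      stop("hub boost exceeds available non-neighbors for node ", node_ids[h])
    }
    new <- if (length(cand) == 1L) cand else sample(cand, hub_degree_boost)
    adj[h, new] <- TRUE
    adj[new, h] <- TRUE
  }
  dimnames(adj) <- list(node_ids, node_ids)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  # vertex order fixed to sorted names for deterministic downstream tie-breaks
  g <- igraph::permute(g, match(igraph::V(g)$name, sort(node_ids)))
  list(graph = g,
       truth = list(planted_hubs = sort(node_ids[hubs]),
                    params = list(n_nodes = n_nodes, n_hubs = n_hubs,
                                  hub_degree_boost = hub_degree_boost,
                                  edge_prob = edge_prob, seed = seed)))
}

#' Generate gene sets enriched for planted signal genes
#'
#' Enriched sets draw at least 80% of members from the union of
#' discriminative genes and trait-linked module genes; null sets are
#' uniform draws from the universe.
#'
#' @param truth Ground-truth list from [generate_expression()].
#' @param n_enriched,n_null Set counts.
#' @param set_size Members per set (<= universe size).
#' @param seed Integer seed.
#' @return Named list of gene vectors (GMT-writable via [write_gmt()]).
#' @export
generate_gene_sets <- function(truth, n_enriched, n_null, set_size, seed) {
  universe <- names(truth$module_label_per_gene)
  if (!length(universe)) stop("empty gene universe")
  if (set_size > length(universe)) stop("set_size exceeds universe")
  set.seed(seed)
  signal <- union(truth$discriminative_genes,
                  universe[truth$module_label_per_gene %in%
                             truth$trait_linked_modules])
  sets <- list()
  for (i in seq_len(n_enriched)) {
    n_sig <- min(ceiling(0.8 * set_size), length(signal))
    mem <- sample(signal, n_sig)
    rest <- setdiff(universe, mem)
    if (set_size > n_sig) mem <- c(mem, sample(rest, set_size - n_sig))
    sets[[paste0("ENRICHED_", i)]] <- mem
  }
  for (i in seq_len(n_null)) {
    sets[[paste0("NULL_", i)]] <- sample(universe, set_size)
  }
  attr(sets, "descriptions") <- stats::setNames(
    c(rep("planted-signal set", n_enriched), rep("uniform null set", n_null)),
    names(sets))
  sets
}

#' Generate a disease-activity (BASDAI-like) severity score
#'
#' Cases receive `coupling * mean(standardized driver expression) + noise`,
#' affinely rescaled into the 0-10 range of the clinical score; controls
#' get missing severity, as the score is defined for patients only.
#'
#' @param phenotypes Phenotype data.frame (group column, "AS" = case).
#' @param expression Gene x sample matrix.
#' @param driver_genes Genes driving severity; must be in the matrix.
#' @param coupling Strength of the expression-severity link.
#' @param seed Integer seed.
#' @param noise_sd Noise standard deviation before rescaling.
#' @return Numeric vector aligned with `phenotypes$sample_id`; NA for
#'   controls.
#' @export
generate_severity <- function(phenotypes, expression, driver_genes,
                              coupling, seed, noise_sd = 1) {
  if (!all(driver_genes %in% rownames(expression))) {
    stop("driver genes missing from expression matrix")
  }
  cases <- phenotypes$group == "AS"
  if (!any(cases)) stop("no case samples")
  set.seed(seed)
  sub <- expression[driver_genes, phenotypes$sample_id[cases], drop = FALSE]
  z <- t(scale(t(sub)))           # per-gene standardization across cases
  raw <- coupling * colMeans(z, na.rm = TRUE) +
    stats::rnorm(sum(cases), sd = noise_sd)
  rng <- range(raw)
  sev <- if (diff(rng) == 0) rep(5, length(raw)) else
    (raw - rng[1L]) / diff(rng) * 10
  out <- rep(NA_real_, nrow(phenotypes))
  out[cases] <- sev
  stats::setNames(out, phenotypes$sample_id)
}

#' Serialize ground truth to JSON
#' @param truth Ground-truth list.
#' @param path Output path.
#' @export
write_ground_truth <- function(truth, path) {
  truth$generating_config <- unclass(truth$generating_config)
  # as.list keeps the gene names (JSON object); a named atomic vector
  # would serialize as a bare array and lose them
  truth$module_label_per_gene <- as.list(truth$module_label_per_gene)
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read ground truth back from JSON
#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  truth <- jsonlite::read_json(path, simplifyVector = TRUE)
  truth$module_label_per_gene <- unlist(truth$module_label_per_gene)
  truth
}
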