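#' Rank genes by a two-group metric
#'
#' Default metric is signal-to-noise: (mean_case - mean_ctrl) /
#' (sd_case + sd_ctrl) with the classic floor on each group sd
#' (sd := max(sd, 0.2 * |mean|); if the group mean is 0, sd := max(sd,
#' 0.2)) so near-constant genes cannot dominate. Groups with fewer than 3
#' samples fall back to the moderated-t metric with a warning. Ordering is
#' by descending score, ties broken by gene id.
#'
#' @param mat Gene x sample matrix.
#' @param phenotypes Phenotype data.frame (group "AS"/"HC").
#' @param metric "signal_to_noise" or "moderated_t".
#' @return Named numeric vector of scores, sorted descending.
#' @export
rank_genes <- function(mat, phenotypes,
                       metric = c("signal_to_noise", "moderated_t")) {
  metric <- match.arg(metric)
  grp <- phenotypes$group[match(colnames(mat), phenotypes$sample_id)]
  case <- grp == "AS"; ctrl <- grp == "HC"
  if (metric == "signal_to_noise" && (sum(case) < 3L || sum(ctrl) < 3L)) {
    warning("fewer than 3 samples per group: falling back to moderated t")
    metric <- "moderated_t"
  }
  if (metric == "signal_to_noise") {
    floor_sd <- function(s, m) {
      lo <- ifelse(m == 0, 0.2, 0.2 * abs(m))
      pmax(s, lo)
    }
    m1 <- rowMeans(mat[, case, drop = FALSE])
    m2 <- rowMeans(mat[, ctrl, drop = FALSE])
    s1 <- floor_sd(apply(mat[, case, drop = FALSE], 1L, stats::sd), m1)
    s2 <- floor_sd(apply(mat[, ctrl, drop = FALSE], 1L, stats::sd), m2)
    score <- (m1 - m2) / (s1 + s2)
  } else {
    tab <- moderated_t_test(mat, phenotypes)
    score <- stats::setNames(tab$t, tab$gene)
  }
  score <- score[order(-score, names(score))]
  score
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list: at a set member the running sum gains
#' |score|^p / sum(|score of members|^p), at a non-member it loses
#' 1/(N - N_hits). The enrichment score is the walk value of largest
#' absolute deviation from zero (signed); the leading edge comprises the
#' members at or before a positive extremum, or at and after a negative
#' one.
#'
#' @param ranked Named score vector, descending (from [rank_genes()]).
#' @param gene_set Character vector of member genes.
#' @param p Weighting exponent (1 = classic weighted; 0 = unweighted KS).
#' @return list(es, walk, leading_edge).
#' @export
enrichment_score <- function(ranked, gene_set, p = 1) {
  genes <- names(ranked)
  hit <- genes %in% gene_set
  n_hits <- sum(hit)
  if (n_hits == 0L) stop("gene set has no overlap with the ranked universe")
  n <- length(genes)
  if (n_hits == n) {
    warning("gene set equals the ranked universe; ES defined as 1")
    return(list(es = 1, walk = cumsum(abs(ranked)^p / sum(abs(ranked)^p)),
                leading_edge = genes))
  }
  w <- abs(ranked)^p
  inc <- ifelse(hit, w / sum(w[hit]), -1 / (n - n_hits))
  walk <- cumsum(inc)
  i_ext <- which.max(abs(walk))
  es <- walk[[i_ext]]
  leading <- if (es >= 0) genes[seq_len(i_ext)][hit[seq_len(i_ext)]] else
    genes[i_ext:n][hit[i_ext:n]]
  list(es = unname(es), walk = unname(walk), leading_edge = leading)
}

#' Permutation p-values for gene-set enrichment
#'
#' In phenotype mode the group labels are permuted and genes re-ranked per
#' permutation (preserving gene-gene correlation); in gene_set mode member
#' labels are resampled on the fixed ranking. p = (1 + #{perm |ES| >=
#' |ES_obs|}) / (n_perm + 1), so p is never 0. Phenotype mode needs at
#' least 7 samples per group, else it switches to gene_set mode with a
#' warning.
#'
#' @param mat Gene x sample matrix (universe = its rows).
#' @param phenotypes Phenotype data.frame.
#' @param sets Named list of gene vectors.
#' @param n_perm Number of permutations (>= 1; >= 100 for reporting).
#' @param mode "phenotype" or "gene_set".
#' @param seed Integer seed.
#' @param p Weighting exponent for [enrichment_score()].
#' @param alpha Significance cut for the `significant` flag.
#' @return data.frame(set, es, p_value, n_members, n_leading, significant).
#' @export
permutation_pvalues <- function(mat, phenotypes, sets, n_perm = 1000,
                                mode = c("phenotype", "gene_set"), seed = 1,
                                p = 1, alpha = 0.05) {
  mode <- match.arg(mode)
  if (n_perm < 1) stop("n_perm must be >= 1")
  grp <- phenotypes$group[match(colnames(mat), phenotypes$sample_id)]
  if (mode == "phenotype" && min(sum(grp == "AS"), sum(grp == "HC")) < 7L) {
    warning("fewer than 7 samples per group: switching to gene_set permutation")
    mode <- "gene_set"
  }
  set.seed(seed)
  ranked <- rank_genes(mat, phenotypes)
  universe <- names(ranked)
  usable <- names(sets)[vapply(sets, function(s) any(s %in% universe), logical(1L))]
  skipped <- setdiff(names(sets), usable)
  if (length(skipped)) {
    message("skipping set(s) with no overlap: ", paste(skipped, collapse = ", "))
  }
  obs <- lapply(sets[usable], function(s) enrichment_score(ranked, s, p = p))
  es_obs <- vapply(obs, `[[`, numeric(1L), "es")
  sizes <- vapply(sets[usable], function(s) sum(s %in% universe), integer(1L))

  exceed <- stats::setNames(numeric(length(usable)), usable)
  if (mode == "phenotype") {
    ph <- phenotypes
    for (b in seq_len(n_perm)) {
      ph$group <- sample(phenotypes$group)
      rk <- rank_genes(mat, ph)
      for (nm in usable) {
        e <- enrichment_score(rk, sets[[nm]], p = p)$es
        if (abs(e) >= abs(es_obs[[nm]])) exceed[[nm]] <- exceed[[nm]] + 1
      }
    }
  } else {
    for (b in seq_len(n_perm)) {
      for (nm in usable) {
        fake <- sample(universe, sizes[[nm]])
        e <- enrichment_score(ranked, fake, p = p)$es
        if (abs(e) >= abs(es_obs[[nm]])) exceed[[nm]] <- exceed[[nm]] + 1
      }
    }
  }
  pv <- (1 + exceed) / (n_perm + 1)
  data.frame(set = usable, es = unname(es_obs), p_value = unname(pv),
             n_members = unname(sizes),
             n_leading = vapply(obs, function(o) length(o$leading_edge),
                                integer(1L)),
             significant = unname(pv) < alpha, row.names = NULL)
}

#' Per-module gene-set enrichment
#'
#' Restricts the ranked universe to one module's genes (mirroring running
#' enrichment per selected module) and reports the top sets by permutation
#' p-value.
#'
#' @param mat Gene x sample matrix.
#' @param phenotypes Phenotype data.frame.
#' @param labels Named module color per gene.
#' @param module Module color whose genes form the universe.
#' @param sets Named list of gene sets.
#' @param top_n Number of top sets to return (default 10).
#' @inheritParams permutation_pvalues
#' @return data.frame sorted by p-value, at most `top_n` rows.
#' @export
gsea_per_module <- function(mat, phenotypes, labels, module, sets,
                            n_perm = 1000, mode = "gene_set", seed = 1,
                            top_n = 10) {
  genes <- names(labels)[labels == module]
  sub <- mat[intersect(rownames(mat), genes), , drop = FALSE]
  res <- permutation_pvalues(sub, phenotypes, sets, n_perm = n_perm,
                             mode = mode, seed = seed)
  res <- res[order(res$p_value, -abs(res$es), res$set), ]
  utils::head(res, top_n)
}
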