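#' ROC AUC with a Mann-Whitney significance test
#'
#' AUC = U / (n1 n2) with ties counted 1/2; the p-value for AUC != 0.5
#' comes from the tie-corrected normal approximation to the Mann-Whitney U
#' statistic, two-sided.
#'
#' @param scores Numeric vector (e.g. one gene's expression).
#' @param labels Binary labels; 1/"AS" = positive class.
#' @return list(auc, p).
#' @export
roc_auc <- function(scores, labels) {
  pos <- labels %in% c(1, "1", "AS", TRUE)
  n1 <- sum(pos); n2 <- sum(!pos)
  if (n1 == 0L || n2 == 0L) stop("both classes must be present")
  r <- rank(scores)
  u <- sum(r[pos]) - n1 * (n1 + 1) / 2
  auc <- u / (n1 * n2)
  p <- if (length(unique(scores)) == 1L) 1 else
    suppressWarnings(stats::wilcox.test(scores[pos], scores[!pos],
                                        exact = FALSE, correct = FALSE)$p.value)
  list(auc = auc, p = p)
}

#' Per-gene ROC screening
#'
#' @param mat Gene x sample matrix.
#' @param phenotypes Phenotype data.frame (group "AS"/"HC").
#' @param genes Candidate genes (default all rows).
#' @return data.frame(gene, auc, p, significant at alpha = 0.05).
#' @export
roc_screen <- function(mat, phenotypes, genes = rownames(mat)) {
  grp <- phenotypes$group[match(colnames(mat), phenotypes$sample_id)]
  res <- lapply(genes, function(g) roc_auc(mat[g, ], grp))
  data.frame(gene = genes,
             auc = vapply(res, `[[`, numeric(1L), "auc"),
             p = vapply(res, `[[`, numeric(1L), "p"),
             row.names = NULL)
}

#' Retain genes whose AUC is significant
#'
#' @param roc data.frame from [roc_screen()].
#' @param alpha Significance level (strict p < alpha).
#' @return list(retained, discarded) gene vectors.
#' @export
screen_significant <- function(roc, alpha = 0.05) {
  keep <- roc$p < alpha
  list(retained = roc$gene[keep], discarded = roc$gene[!keep])
}

#' One-way ANOVA of expression between the two groups
#'
#' Equal-variance one-way ANOVA (for two groups, F equals the squared
#' pooled t-statistic). Genes constant across all samples get F = 0 and
#' p = 1 with a warning.
#'
#' @param mat Gene x sample matrix.
#' @param phenotypes Phenotype data.frame.
#' @param genes Genes to test (default all).
#' @param alpha Flagging threshold (default 0.01).
#' @return data.frame(gene, f, p, significant).
#' @export
group_difference_test <- function(mat, phenotypes, genes = rownames(mat),
                                  alpha = 0.01) {
  grp <- factor(phenotypes$group[match(colnames(mat), phenotypes$sample_id)])
  if (any(table(grp) < 2L)) stop("each group needs at least 2 samples")
  res <- t(vapply(genes, function(g) {
    x <- mat[g, ]
    if (stats::sd(x) == 0) {
      warning("constant gene: ", g)
      return(c(0, 1))
    }
    ow <- stats::oneway.test(x ~ grp, var.equal = TRUE)
    c(unname(ow$statistic), ow$p.value)
  }, numeric(2L)))
  data.frame(gene = genes, f = res[, 1L], p = res[, 2L],
             significant = res[, 2L] < alpha, row.names = NULL)
}

#' Correlation of gene expression with disease severity among cases
#'
#' Pearson r with a two-sided Student-t p-value (df = n - 2), computed on
#' case samples with non-missing severity only (controls carry no score).
#'
#' @param mat Gene x sample matrix.
#' @param phenotypes Phenotype data.frame with a severity column.
#' @param genes Genes to test.
#' @param alpha Significance level (default 0.05).
#' @return data.frame(gene, r, r_squared, p, significant, n).
#' @export
severity_correlation <- function(mat, phenotypes, genes = rownames(mat),
                                 alpha = 0.05) {
  if (is.null(phenotypes$severity)) stop("phenotype table has no severity column")
  use <- phenotypes$group == "AS" & !is.na(phenotypes$severity)
  ids <- phenotypes$sample_id[use]
  if (length(ids) < 3L) stop("need at least 3 cases with severity")
  sev <- phenotypes$severity[use]
  res <- t(vapply(genes, function(g) {
    ct <- stats::cor.test(mat[g, ids], sev)
    c(unname(ct$estimate), ct$p.value)
  }, numeric(2L)))
  data.frame(gene = genes, r = res[, 1L], r_squared = res[, 1L]^2,
             p = res[, 2L], significant = res[, 2L] < alpha,
             n = length(ids), row.names = NULL)
}

#' Adjusted Rand index between two labelings
#'
#' @param a,b Label vectors of equal length.
#' @return ARI in [-1, 1]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  mclust::adjustedRandIndex(a, b)
}

.precision_recall <- function(selected, truth) {
  tp <- length(intersect(selected, truth))
  list(precision = if (length(selected)) tp / length(selected) else NA_real_,
       recall = if (length(truth)) tp / length(truth) else NA_real_)
}

#' Score pipeline outputs against synthetic ground truth
#'
#' Module recovery is the adjusted Rand index between detected and planted
#' labels over genes with a planted (non-background) module; DE, hub and
#' key-gene sets are scored by precision and recall against the planted
#' discriminative genes and planted hubs.
#'
#' @param truth Ground-truth list from [generate_expression()] (optionally
#'   with planted_hubs filled in from [generate_ppi_graph()]).
#' @param module_labels Named detected color per gene (optional).
#' @param de_genes Detected DE genes (optional).
#' @param hubs Detected hub nodes (optional).
#' @param key_genes Selected key genes (optional).
#' @return list of metrics, each NULL when its input is missing.
#' @export
recovery_metrics <- function(truth, module_labels = NULL, de_genes = NULL,
                             hubs = NULL, key_genes = NULL) {
  if (is.null(truth)) stop("ground truth required")
  out <- list()
  if (!is.null(module_labels)) {
    planted <- truth$module_label_per_gene
    genes <- names(planted)[planted != "background"]
    genes <- intersect(genes, names(module_labels))
    out$module_ari <- adjusted_rand_index(planted[genes], module_labels[genes])
  }
  if (!is.null(de_genes)) {
    out$de <- .precision_recall(de_genes, truth$discriminative_genes)
    # a false discovery is a gene with no planted group effect at all:
    # trait-linked module genes carry a real (factor-mediated) shift, so
    # they are excluded from the null set
    affected <- union(
      truth$discriminative_genes,
      names(truth$module_label_per_gene)[truth$module_label_per_gene %in%
                                           truth$trait_linked_modules])
    out$de$fdp_null <- if (length(de_genes)) {
      length(setdiff(de_genes, affected)) / length(de_genes)
    } else NA_real_
  }
  if (!is.null(hubs)) {
    out$hubs <- .precision_recall(hubs, truth$planted_hubs)
  }
  if (!is.null(key_genes)) {
    out$key_genes <- .precision_recall(key_genes, truth$discriminative_genes)
  }
  out
}
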