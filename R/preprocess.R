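#' K-nearest-neighbor imputation of missing expression values
#'
#' Classical gene-wise KNN imputation: for each gene with missing cells,
#' the k genes nearest in Euclidean distance (over samples where both
#' genes are observed, scaled to per-sample distance) supply the imputed
#' value as their mean at the missing sample, restricted to neighbor genes
#' observed there. Observed cells are never altered, so a second pass is a
#' no-op.
#'
#' @param mat Gene x sample matrix with NA for missing.
#' @param k Number of neighbor genes (default 10).
#' @return Completed matrix.
#' @export
knn_impute <- function(mat, k = 10) {
  stopifnot(k >= 1)
  obs_per_gene <- rowSums(!is.na(mat))
  if (any(obs_per_gene < 2L)) {
    stop("gene(s) with fewer than 2 observed values: ",
         paste(rownames(mat)[obs_per_gene < 2L], collapse = ", "))
  }
  miss_genes <- which(rowSums(is.na(mat)) > 0L)
  if (!length(miss_genes)) return(mat)
  out <- mat
  for (g in miss_genes) {
    x <- mat[g, ]
    diffs <- sweep(mat, 2L, x)          # gene rows minus target gene
    sq <- diffs^2
    shared <- rowSums(!is.na(sq))
    d <- sqrt(rowMeans(sq, na.rm = TRUE))
    d[g] <- Inf
    d[shared == 0L] <- Inf
    for (s in which(is.na(x))) {
      cand <- which(!is.na(mat[, s]) & is.finite(d))
      if (!length(cand)) {
        stop("no donor genes observed at sample ", colnames(mat)[s])
      }
      nb <- cand[order(d[cand], cand)][seq_len(min(k, length(cand)))]
      out[g, s] <- mean(mat[nb, s])
    }
  }
  out
}

#' Per-batch location adjustment
#'
#' Shifts each batch's per-gene mean to the gene's grand mean, removing
#' additive batch offsets while preserving gene-wise grand means. This is
#' a location-only adjustment, not empirical-Bayes batch correction; it is
#' exact for the additive batch model the synthetic generator uses.
#'
#' @param mat Gene x sample matrix.
#' @param phenotypes Phenotype data.frame with sample_id and batch columns.
#' @return Adjusted matrix (unchanged, with a message, for a single batch).
#' @export
adjust_batches <- function(mat, phenotypes) {
  if (is.null(phenotypes$batch)) stop("phenotype table has no batch column")
  batch <- phenotypes$batch[match(colnames(mat), phenotypes$sample_id)]
  if (anyNA(batch)) stop("batch labels missing for some samples")
  if (length(unique(batch)) < 2L) {
    message("single batch: no adjustment performed")
    return(mat)
  }
  grand <- rowMeans(mat, na.rm = TRUE)
  out <- mat
  for (b in unique(batch)) {
    cols <- batch == b
    bm <- rowMeans(mat[, cols, drop = FALSE], na.rm = TRUE)
    out[, cols] <- mat[, cols, drop = FALSE] - bm + grand
  }
  out
}

#' Keep the most variable genes
#'
#' Retains the ceil(top_fraction * n_genes) genes with the highest sample
#' variance (denominator n-1), the usual noise-reduction step before
#' co-expression network construction. Ties are broken by gene id
#' (lexicographic) for determinism.
#'
#' @param mat Gene x sample matrix.
#' @param top_fraction Fraction of genes to keep, in (0, 1].
#' @return Row-subset matrix in original row order restricted to kept genes.
#' @export
variance_filter <- function(mat, top_fraction = 0.25) {
  if (top_fraction <= 0 || top_fraction > 1) stop("top_fraction must be in (0,1]")
  if (ncol(mat) < 2L) stop("variance undefined with fewer than 2 samples")
  v <- apply(mat, 1L, stats::var, na.rm = TRUE)
  n_keep <- ceiling(top_fraction * nrow(mat))
  ord <- order(-v, rownames(mat))
  keep <- sort(ord[seq_len(n_keep)])
  mat[keep, , drop = FALSE]
}

#' Run imputation, batch adjustment and variance filtering
#'
#' Fixed order: impute -> batch-adjust -> variance filter.
#'
#' @param mat Gene x sample matrix.
#' @param phenotypes Phenotype data.frame.
#' @param k KNN neighbors.
#' @param top_fraction Variance-filter fraction.
#' @param adjust Whether to batch-adjust (needs a batch column).
#' @return list(expression = filtered matrix, report = counts).
#' @export
preprocess_expression <- function(mat, phenotypes, k = 10,
                                  top_fraction = 0.25, adjust = TRUE) {
  n_missing <- sum(is.na(mat))
  imp <- knn_impute(mat, k = k)
  adj <- if (adjust && !is.null(phenotypes$batch)) {
    adjust_batches(imp, phenotypes)
  } else imp
  filt <- variance_filter(adj, top_fraction)
  list(expression = filt,
       report = list(n_imputed_cells = n_missing,
                     n_genes_before = nrow(mat),
                     n_genes_after = nrow(filt),
                     variance_quantile_used = top_fraction,
                     batch_adjusted = adjust && !is.null(phenotypes$batch) &&
                       length(unique(phenotypes$batch)) > 1L))
}
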