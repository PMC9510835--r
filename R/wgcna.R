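#' Scale-free topology fit index
#'
#' Bins the connectivity distribution into equal-width bins and regresses
#' log10(frequency) on log10(mean connectivity) over non-empty bins. The
#' fit index is R-squared signed by the negated slope, so a network whose
#' degree distribution follows a decaying power law (the scale-free
#' signature) scores near +1 and an increasing one scores negatively.
#'
#' @param k Non-negative connectivity vector.
#' @param n_bins Number of equal-width bins (default 10).
#' @return list(r_squared = signed R^2, slope).
#' @export
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < 2L) stop("degenerate connectivity: all values equal")
  cuts <- seq(min(k), max(k), length.out = n_bins + 1L)
  bin <- findInterval(k, cuts, rightmost.closed = TRUE)
  bin[bin > n_bins] <- n_bins
  freq <- tabulate(bin, nbins = n_bins)
  keep <- freq > 0
  if (sum(keep) < 2L) stop("degenerate connectivity: fewer than 2 occupied bins")
  mean_k <- vapply(which(keep), function(b) mean(k[bin == b]), numeric(1L))
  x <- log10(mean_k)
  y <- log10(freq[keep] / length(k))
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2L])
  # suppressed: summary.lm warns on constructed exact power laws
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(r_squared = -r2 * sign(slope), slope = slope)
}

#' Soft-threshold (power) scan for approximate scale-free topology
#'
#' For each candidate power beta, builds the adjacency |cor|^beta (or the
#' signed variant), computes each gene's connectivity k_i = sum_j a_ij,
#' and evaluates the scale-free fit index. The chosen beta is the smallest
#' candidate whose signed R^2 reaches `r2_cut`; if none does, the beta
#' maximizing the index is returned with a warning. Mean connectivity is
#' reported for inspection but plays no part in the choice.
#'
#' @param mat Gene x sample matrix (complete; impute first).
#' @param powers Candidate integer powers.
#' @param r2_cut Signed R^2 adequacy cut (default 0.9).
#' @param mode "unsigned" (|cor|^beta) or "signed" (((1+cor)/2)^beta).
#' @param n_bins Bins for [scale_free_fit()].
#' @return list(scan = data.frame(power, r_squared, slope, mean_k),
#'   beta = chosen power).
#' @export
pick_soft_threshold <- function(mat, powers = 1:20, r2_cut = 0.9,
                                mode = c("unsigned", "signed"), n_bins = 10) {
  mode <- match.arg(mode)
  if (ncol(mat) < 3L) stop("need at least 3 samples")
  cm <- stats::cor(t(mat))
  base <- if (mode == "unsigned") abs(cm) else (1 + cm) / 2
  diag(base) <- 0
  res <- data.frame(power = powers, r_squared = NA_real_,
                    slope = NA_real_, mean_k = NA_real_)
  for (i in seq_along(powers)) {
    a <- base^powers[i]
    k <- rowSums(a)
    res$mean_k[i] <- mean(k)
    fit <- tryCatch(scale_free_fit(k, n_bins = n_bins), error = function(e) e)
    if (inherits(fit, "error")) {
      warning("power ", powers[i], ": ", conditionMessage(fit))
      next
    }
    res$r_squared[i] <- fit$r_squared
    res$slope[i] <- fit$slope
  }
  if (all(is.na(res$r_squared))) {
    stop("scale-free fit failed at every power (degenerate input)")
  }
  ok <- which(!is.na(res$r_squared) & res$r_squared >= r2_cut)
  if (length(ok)) {
    beta <- powers[min(ok)]
  } else {
    beta <- powers[which.max(res$r_squared)]
    warning("no power reached R^2 >= ", r2_cut,
            "; using power with maximal fit index (", beta, ")")
  }
  list(scan = res, beta = beta)
}

#' Correlation-to-adjacency transform
#'
#' @param cor_mat Correlation matrix in [-1, 1].
#' @param beta Soft-threshold power (>= 1).
#' @param mode "unsigned": a_ij = |cor|^beta; "signed": ((1+cor)/2)^beta.
#' @return Adjacency matrix in [0, 1]; the diagonal is set to 0 so
#'   connectivity sums exclude self-adjacency.
#' @export
adjacency_from_cor <- function(cor_mat, beta, mode = c("unsigned", "signed")) {
  mode <- match.arg(mode)
  if (beta < 1) stop("beta must be >= 1")
  a <- if (mode == "unsigned") abs(cor_mat)^beta else ((1 + cor_mat) / 2)^beta
  diag(a) <- 0
  a
}

#' Topological overlap similarity
#'
#' TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij) with
#' l_ij = sum_u a_iu a_uj and k_i the connectivity; TOM_ii = 1. High
#' overlap means two genes share neighbors as well as a direct link, which
#' is what the module clustering dissimilarity 1 - TOM is built on.
#'
#' @param adj Adjacency matrix with zero diagonal.
#' @return TOM matrix.
#' @export
tom_similarity <- function(adj) {
  a <- adj
  diag(a) <- 0
  l <- a %*% a
  k <- rowSums(a)
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

# Fixed module color vocabulary, assigned by decreasing module size;
# "grey" is reserved for unassigned genes.
.module_colors <- c("turquoise", "blue", "brown", "yellow", "green", "red",
                    "black", "pink", "magenta", "purple", "greenyellow",
                    "tan", "salmon", "cyan", "midnightblue", "lightcyan",
                    "grey60", "lightgreen", "lightyellow", "royalblue")

#' Module eigengene of an expression submatrix
#'
#' First right-singular vector of the gene-standardized submatrix (unit
#' norm over samples), sign-flipped so its correlation with the module's
#' mean standardized profile is non-negative. The proportion of variance
#' explained is the leading singular value's share of the total.
#'
#' @param sub Gene x sample matrix of one module (>= 2 genes, >= 3 samples).
#' @return list(eigengene, var_explained).
#' @export
module_eigengene <- function(sub) {
  if (nrow(sub) < 2L || ncol(sub) < 3L) {
    stop("module eigengene needs >= 2 genes and >= 3 samples")
  }
  sds <- apply(sub, 1L, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance gene(s): ",
            paste(rownames(sub)[sds == 0], collapse = ", "))
    sub <- sub[sds > 0, , drop = FALSE]
    if (nrow(sub) < 2L) stop("too few non-constant genes in module")
  }
  z <- t(scale(t(sub)))
  sv <- svd(z)
  e <- sv$v[, 1L]
  if (stats::cor(e, colMeans(z)) < 0) e <- -e
  list(eigengene = stats::setNames(e, colnames(sub)),
       var_explained = sv$d[1L]^2 / sum(sv$d^2))
}

.eigengene_matrix <- function(mat, labels) {
  mods <- setdiff(unique(labels), "grey")
  me <- sapply(mods, function(m) {
    module_eigengene(mat[labels == m, , drop = FALSE])$eigengene
  })
  me <- matrix(me, ncol = length(mods),
               dimnames = list(colnames(mat), mods))
  me
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering on the dissimilarity 1 - TOM;
#' clusters smaller than `min_size` are assigned to "grey". Modules whose
#' eigengenes are closer than `merge_cut` in correlation dissimilarity
#' (1 - cor) are merged iteratively until stable. Colors come from the
#' conventional module palette in decreasing size order.
#'
#' By default the tree is cut adaptively: among the nested partitions
#' `cutree(hc, k = 1..k_max)` the one producing the most clusters of at
#' least `min_size` genes is chosen, with ties going to the coarsest
#' partition. This replaces a fixed cut height because raising the
#' soft-threshold power compresses topological-overlap dissimilarities
#' toward 1, so no single absolute height separates modules across powers;
#' any oversplitting the rule introduces is undone by the eigengene merge
#' step. Passing a numeric `cut_height` forces a classical static cut at
#' that height instead.
#'
#' @param tom TOM matrix (genes in rows/cols, named).
#' @param mat The gene x sample expression matrix the TOM came from
#'   (needed for eigengene computation during merging).
#' @param min_size Minimum module size (default 30).
#' @param cut_height NULL (default) for the adaptive cut, or a height in
#'   (0, 1] for a static cut on 1 - TOM.
#' @param merge_cut Eigengene dissimilarity below which modules merge.
#' @param k_max Largest cluster count examined by the adaptive cut.
#' @return list(labels = named color per gene, sizes, eigengenes = sample x
#'   module matrix, var_explained, dendrogram = hclust object).
#' @export
detect_modules <- function(tom, mat, min_size = 30, cut_height = NULL,
                           merge_cut = 0.25, k_max = 200) {
  stopifnot(identical(rownames(tom), rownames(mat)))
  genes <- rownames(tom)
  if (length(genes) < min_size) {
    warning("fewer genes than min_size: all genes unassigned")
    labels <- stats::setNames(rep("grey", length(genes)), genes)
    return(list(labels = labels, sizes = integer(0), eigengenes = NULL,
                var_explained = numeric(0), dendrogram = NULL))
  }
  diss <- 1 - tom
  hc <- stats::hclust(stats::as.dist(diss), method = "average")
  if (is.null(cut_height)) {
    ks <- seq_len(min(k_max, length(genes) - 1L))
    parts <- stats::cutree(hc, k = ks)
    n_big <- apply(parts, 2L, function(cl) sum(table(cl) >= min_size))
    cl <- parts[, which.max(n_big)]   # which.max: ties -> coarsest
  } else {
    cl <- stats::cutree(hc, h = cut_height)
  }
  sizes <- table(cl)
  cl[cl %in% as.integer(names(sizes)[sizes < min_size])] <- 0L

  if (all(cl == 0L)) {
    warning("no cluster reached min_size: all genes unassigned")
    labels <- stats::setNames(rep("grey", length(genes)), genes)
    return(list(labels = labels, sizes = integer(0), eigengenes = NULL,
                var_explained = numeric(0), dendrogram = hc))
  }

  labels <- ifelse(cl == 0L, "grey", paste0("m", cl))
  names(labels) <- genes

  # iterative eigengene merging: join the closest pair under merge_cut
  repeat {
    mods <- setdiff(unique(labels), "grey")
    if (length(mods) < 2L) break
    me <- .eigengene_matrix(mat, labels)
    d <- 1 - stats::cor(me)
    diag(d) <- Inf
    if (min(d) >= merge_cut) break
    pair <- which(d == min(d), arr.ind = TRUE)[1L, ]
    keep <- colnames(d)[pair[["col"]]]
    drop <- rownames(d)[pair[["row"]]]
    labels[labels == drop] <- keep
  }

  mods <- setdiff(unique(labels), "grey")
  sz <- sort(table(labels[labels != "grey"]), decreasing = TRUE)
  palette <- c(.module_colors, paste0("module", seq_len(max(0, length(mods) -
                                                       length(.module_colors)))))
  color_of <- stats::setNames(palette[seq_along(sz)], names(sz))
  labels[labels != "grey"] <- color_of[labels[labels != "grey"]]

  me_final <- .eigengene_matrix(mat, labels)
  ve <- vapply(colnames(me_final), function(m) {
    module_eigengene(mat[labels == m, , drop = FALSE])$var_explained
  }, numeric(1L))
  list(labels = labels,
       sizes = table(labels[labels != "grey"]),
       eigengenes = me_final,
       var_explained = ve,
       dendrogram = hc)
}

#' Module-trait correlation and selection
#'
#' Pearson correlation of each module eigengene with the binary trait
#' (1 = AS, 0 = HC) and a two-sided Student-t p-value (df = n - 2). A
#' module is selected when |r| meets the cutoff. The grey (unassigned)
#' bin may be passed in as a column and is eligible for selection, but is
#' flagged in the output so reports can call it out.
#'
#' @param eigengenes Sample x module matrix.
#' @param phenotypes Phenotype data.frame (group column).
#' @param cutoff Absolute-correlation selection cutoff (default 0.3).
#' @return data.frame(module, r, p, selected, is_grey).
#' @export
module_trait_correlation <- function(eigengenes, phenotypes, cutoff = 0.3) {
  trait <- as.numeric(phenotypes$group[match(rownames(eigengenes),
                                             phenotypes$sample_id)] == "AS")
  if (anyNA(trait)) stop("samples missing from phenotype table")
  if (stats::sd(trait) == 0) stop("trait is constant")
  n <- length(trait)
  r <- apply(eigengenes, 2L, function(e) {
    if (stats::sd(e) == 0) stop("constant eigengene")
    stats::cor(e, trait)
  })
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  data.frame(module = colnames(eigengenes), r = r, p = p,
             selected = abs(r) >= cutoff,
             is_grey = colnames(eigengenes) == "grey",
             row.names = NULL)
}

#' Gene significance and module membership
#'
#' GS_g = |cor(x_g, trait)|; MM_{g,m} = cor(x_g, eigengene_m). For each
#' module, the correlation of MM with GS over its genes (with a Student-t
#' p-value) summarizes whether central module members also track the
#' trait.
#'
#' @param mat Gene x sample matrix.
#' @param eigengenes Sample x module matrix.
#' @param phenotypes Phenotype data.frame.
#' @param labels Named module color per gene (for the per-module summary).
#' @return list(gs = named vector, mm = gene x module matrix,
#'   module_summary = data.frame(module, cor_mm_gs, p, n_genes)).
#' @export
gene_trait_stats <- function(mat, eigengenes, phenotypes, labels = NULL) {
  trait <- as.numeric(phenotypes$group[match(colnames(mat),
                                             phenotypes$sample_id)] == "AS")
  sds <- apply(mat, 1L, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant gene(s): ",
            paste(rownames(mat)[sds == 0], collapse = ", "))
    mat <- mat[sds > 0, , drop = FALSE]
    if (!is.null(labels)) labels <- labels[rownames(mat)]
  }
  gs <- abs(as.vector(stats::cor(t(mat), trait)))
  names(gs) <- rownames(mat)
  mm <- stats::cor(t(mat), eigengenes)
  summary_df <- NULL
  if (!is.null(labels)) {
    mods <- intersect(colnames(eigengenes), unique(labels))
    summary_df <- do.call(rbind, lapply(mods, function(m) {
      gset <- names(labels)[labels == m]
      gset <- intersect(gset, rownames(mm))
      if (length(gset) < 3L) {
        return(data.frame(module = m, cor_mm_gs = NA_real_, p = NA_real_,
                          n_genes = length(gset)))
      }
      ct <- stats::cor.test(mm[gset, m], gs[gset])
      data.frame(module = m, cor_mm_gs = unname(ct$estimate),
                 p = ct$p.value, n_genes = length(gset))
    }))
  }
  list(gs = gs, mm = mm, module_summary = summary_df)
}

#' Permutation Z-score of module preservation
#'
#' A simplified preservation statistic: the observed mean intramodular
#' adjacency of each module is compared with its distribution under
#' uniformly random reassignment of module labels;
#' Z = (obs - mean(perm)) / sd(perm). Strongly coherent modules score
#' large positive Z, random gene subsets score near 0.
#'
#' @param mat Gene x sample matrix.
#' @param labels Named module color per gene ("grey" excluded).
#' @param n_permutations Number of label permutations (>= 1).
#' @param seed Integer seed.
#' @param beta Soft-threshold power for the adjacency (default 6).
#' @return Named numeric vector of Z scores per module.
#' @export
preservation_z <- function(mat, labels, n_permutations = 100, seed = 1,
                           beta = 6) {
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  mods <- setdiff(unique(labels), "grey")
  if (!length(mods)) stop("no non-grey modules")
  set.seed(seed)
  a <- adjacency_from_cor(stats::cor(t(mat)), beta)
  mean_intra <- function(lab) {
    vapply(mods, function(m) {
      idx <- which(lab == m)
      if (length(idx) < 2L) return(NA_real_)
      block <- a[idx, idx]
      sum(block) / (length(idx) * (length(idx) - 1L))
    }, numeric(1L))
  }
  obs <- mean_intra(labels[rownames(mat)])
  perm <- replicate(n_permutations, mean_intra(
    stats::setNames(sample(labels), names(labels))[rownames(mat)]))
  perm <- matrix(perm, nrow = length(mods))
  mu <- rowMeans(perm)
  sdev <- apply(perm, 1L, stats::sd)
  z <- (obs - mu) / sdev
  if (any(sdev == 0)) {
    warning("zero permutation sd for module(s): ",
            paste(mods[sdev == 0], collapse = ", "))
    z[sdev == 0] <- Inf * sign(obs - mu)[sdev == 0]
  }
  stats::setNames(z, mods)
}
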