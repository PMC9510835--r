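#' Empirical-Bayes variance prior by moment matching on log variances
#'
#' Models gene-wise residual variances as s^2_g ~ s0^2 * chi^2_{d_g}/d_g
#' scaled by an inverse-chi-square prior with d0 degrees of freedom, and
#' estimates (d0, s0^2) from the spread of e_g = log s^2_g: d0 solves
#' trigamma(d0/2) = var(e) - mean(trigamma(d_g/2)) by monotone bisection.
#' When the observed spread is no larger than sampling noise alone, d0 is
#' infinite and s0^2 is the mean variance (complete shrinkage).
#'
#' @param s2 Gene-wise residual variances (> 0), length >= 10.
#' @param df Residual degrees of freedom, scalar or per-gene (>= 1).
#' @return list(d0, s0_sq).
#' @export
fit_variance_prior <- function(s2, df) {
  if (length(s2) < 10L) stop("need at least 10 genes to fit the variance prior")
  if (any(s2 <= 0)) stop("non-positive residual variance")
  if (any(df < 1)) stop("residual df must be >= 1")
  df <- rep_len(df, length(s2))
  e <- log(s2)
  target <- stats::var(e) - mean(trigamma(df / 2))
  if (target <= 0) {
    return(list(d0 = Inf, s0_sq = mean(s2)))
  }
  # trigamma is strictly decreasing: bisect for d0/2 on (1e-6, 1e7)
  f <- function(half_d0) trigamma(half_d0) - target
  lo <- 1e-6; hi <- 1e7
  if (f(lo) < 0) return(list(d0 = 2 * lo, s0_sq = NA_real_))
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  d0 <- 2 * (lo + hi) / 2
  s0_sq <- exp(mean(e) - mean(digamma(df / 2) - log(df / 2)) +
                 digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0_sq)
}

#' Moderated two-group t-test
#'
#' Per-gene two-group comparison (AS vs HC) with the pooled variance
#' shrunk toward the empirical-Bayes prior:
#' s~^2 = (d0 s0^2 + d_g s^2_g) / (d0 + d_g), t~ = log2FC / (s~ sqrt(1/n1
#' + 1/n2)), two-sided p from Student t with d0 + d_g degrees of freedom
#' (standard normal when d0 is infinite). Benjamini-Hochberg adjusted
#' p-values are appended. `d0_override = 0` recovers the ordinary
#' two-sample t-statistic.
#'
#' @param mat Gene x sample log2 matrix.
#' @param phenotypes Phenotype data.frame (group column, "AS"/"HC").
#' @param d0_override Optional fixed prior df (bypasses estimation).
#' @return data.frame(gene, log2fc, t, p, adj_p, direction).
#' @export
moderated_t_test <- function(mat, phenotypes, d0_override = NULL) {
  grp <- phenotypes$group[match(colnames(mat), phenotypes$sample_id)]
  case <- grp == "AS"; ctrl <- grp == "HC"
  n1 <- sum(case); n2 <- sum(ctrl)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 samples")
  m1 <- rowMeans(mat[, case, drop = FALSE])
  m2 <- rowMeans(mat[, ctrl, drop = FALSE])
  v1 <- apply(mat[, case, drop = FALSE], 1L, stats::var)
  v2 <- apply(mat[, ctrl, drop = FALSE], 1L, stats::var)
  dg <- n1 + n2 - 2
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / dg
  lfc <- m1 - m2

  if (is.null(d0_override)) {
    pr <- fit_variance_prior(pmax(s2, 1e-12), dg)
    d0 <- pr$d0; s0 <- pr$s0_sq
  } else {
    d0 <- d0_override
    s0 <- if (d0 > 0) mean(s2) else 0
  }
  s2_tilde <- if (is.infinite(d0)) rep(s0, length(s2)) else
    (d0 * s0 + dg * s2) / (d0 + dg)
  se <- sqrt(s2_tilde * (1 / n1 + 1 / n2))
  tstat <- ifelse(se == 0, 0, lfc / se)
  df_total <- d0 + dg
  p <- if (is.infinite(df_total)) 2 * stats::pnorm(-abs(tstat)) else
    2 * stats::pt(-abs(tstat), df = df_total)
  p[se == 0 & lfc == 0] <- 1
  data.frame(gene = rownames(mat), log2fc = lfc, t = tstat, p = p,
             adj_p = bh_adjust(p),
             direction = ifelse(lfc > 0, "up", ifelse(lfc < 0, "down", "none")),
             row.names = NULL)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' adj_(i) = min over j >= i of min(1, p_(j) m / j) in ascending order,
#' mapped back to the input order (the standard FDR-controlling step-up).
#'
#' @param p Vector of p-values in [0, 1].
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Apply the differential-expression filters
#'
#' Up = adjusted p strictly below `p_cut` and log2FC strictly above
#' `lfc_cut`; down symmetric. The fold-change cut is on the log2 scale
#' (|log2FC| > 1 means two-fold), since a natural-scale cut of 1 would
#' exclude nothing.
#'
#' @param table Output of [moderated_t_test()].
#' @param p_cut Adjusted-p cutoff (default 0.01).
#' @param lfc_cut log2 fold-change cutoff (default 1).
#' @return list(up, down) gene id vectors.
#' @export
filter_de <- function(table, p_cut = 0.01, lfc_cut = 1) {
  list(up = table$gene[table$adj_p < p_cut & table$log2fc > lfc_cut],
       down = table$gene[table$adj_p < p_cut & table$log2fc < -lfc_cut])
}

#' Intersect differentially expressed genes with selected-module genes
#'
#' @param de_genes Character vector (up and down combined).
#' @param labels Named module color per gene.
#' @param selected_modules Module colors chosen by trait correlation.
#' @return Character vector of feature genes.
#' @export
intersect_with_modules <- function(de_genes, labels, selected_modules) {
  module_genes <- names(labels)[labels %in% selected_modules]
  out <- intersect(module_genes, de_genes)
  if (!length(out)) warning("empty intersection of module and DE genes")
  sort(out)
}
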