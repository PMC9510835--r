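# internal: linear SVM squared-weight criterion per feature
.svm_weights_sq <- function(X, y, C) {
  fit <- e1071::svm(X, factor(y), kernel = "linear", cost = C, scale = FALSE)
  w <- as.vector(t(fit$coefs) %*% fit$SV)
  w^2
}

# internal: train-set standardization (constant features map to 0)
.standardize <- function(X, center = NULL, scale_ = NULL) {
  if (is.null(center)) {
    center <- colMeans(X)
    scale_ <- apply(X, 2L, stats::sd)
  }
  scale_[scale_ == 0] <- 1
  Z <- sweep(sweep(X, 2L, center), 2L, scale_, "/")
  attr(Z, "center") <- center
  attr(Z, "scale") <- scale_
  Z
}

#' SVM recursive feature elimination ranking
#'
#' Backward elimination: fit a linear max-margin classifier on the
#' surviving features (standardized to training mean/sd), score each
#' feature by its squared weight w_i^2, discard the `step` lowest-scoring
#' features (ties: the higher feature index is removed first), and repeat
#' until none remain. Features removed later are more informative; rank 1
#' is the last-removed feature. A linear kernel is used for the ranking
#' because the weight vector w is only defined for linear decision
#' functions.
#'
#' @param X Samples x features numeric matrix (named columns).
#' @param y Binary labels (two levels; "AS"/"HC" or 0/1).
#' @param step Features removed per iteration (default 1).
#' @param C Soft-margin cost (default 1).
#' @param seed Integer seed (the e1071 fit is deterministic; the seed is
#'   kept for interface symmetry with the stochastic stages).
#' @return list(ranking = named ranks (1 = best), elimination_order =
#'   feature ids first-removed to last-removed, criteria = last computed
#'   w^2 per feature).
#' @export
rfe_rank <- function(X, y, step = 1, C = 1, seed = 1) {
  stopifnot(is.matrix(X), !is.null(colnames(X)))
  y <- factor(y)
  if (nlevels(y) != 2L || min(table(y)) < 2L) {
    stop("need two classes with at least 2 samples each")
  }
  set.seed(seed)
  features <- colnames(X)
  surviving <- seq_along(features)
  removed <- integer(0)
  crit_last <- stats::setNames(numeric(length(features)), features)
  while (length(surviving) > 0L) {
    if (length(surviving) == 1L) {
      removed <- c(removed, surviving)
      break
    }
    Z <- .standardize(X[, surviving, drop = FALSE])
    c_i <- .svm_weights_sq(Z, y, C)
    crit_last[surviving] <- c_i
    # remove `step` smallest criteria; ties -> larger index removed first
    ord <- order(c_i, -surviving)
    drop_local <- ord[seq_len(min(step, length(surviving)))]
    removed <- c(removed, surviving[drop_local])
    surviving <- surviving[-drop_local]
  }
  elimination_order <- features[removed]
  ranking <- stats::setNames(rev(seq_along(features))[match(features,
                                                            elimination_order)],
                             features)
  list(ranking = ranking,
       elimination_order = elimination_order,
       criteria = crit_last)
}

# internal: stratified fold assignment, seeded
.stratified_folds <- function(y, n_folds, seed) {
  y <- factor(y)
  if (any(table(y) < n_folds)) {
    # every fold must see both classes in training; with very small
    # classes this cannot always hold for testing, but training works as
    # long as each class has >= 2 members outside any fold
    if (any(table(y) < 2L)) stop("cannot stratify: a class has < 2 samples")
  }
  set.seed(seed)
  fold <- integer(length(y))
  for (lv in levels(y)) {
    idx <- sample(which(y == lv))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Cross-validated error curve over nested feature sets
#'
#' For each k (number of top-ranked features), trains the classifier on
#' the training folds restricted to those features and records the
#' held-out misclassification rate, using seeded stratified folds. The
#' optimum k* minimizes the mean error; ties go to the smallest k.
#' Standardization parameters are computed inside each training fold only.
#'
#' @param X Samples x features matrix.
#' @param y Binary labels.
#' @param ranking Named rank vector from [rfe_rank()].
#' @param n_folds Number of folds (default 5).
#' @param kernel e1071 kernel for the CV classifier ("linear" default;
#'   "radial" available).
#' @param C Soft-margin cost.
#' @param seed Integer seed for the fold shuffle.
#' @return list(curve = data.frame(k, mean_error, fold errors...),
#'   k_star, folds).
#' @export
cv_error_curve <- function(X, y, ranking, n_folds = 5,
                           kernel = c("linear", "radial"), C = 1, seed = 1) {
  kernel <- match.arg(kernel)
  if (n_folds < 2L) stop("n_folds must be >= 2")
  y <- factor(y)
  fold <- .stratified_folds(y, n_folds, seed)
  ord_features <- names(sort(ranking))
  p <- length(ord_features)
  errs <- matrix(NA_real_, p, n_folds)
  for (f in seq_len(n_folds)) {
    tr <- fold != f; te <- fold == f
    if (nlevels(droplevels(y[tr])) < 2L) stop("training fold lacks a class")
    for (k in seq_len(p)) {
      feats <- ord_features[seq_len(k)]
      Ztr <- .standardize(X[tr, feats, drop = FALSE])
      Zte <- .standardize(X[te, feats, drop = FALSE],
                          attr(Ztr, "center"), attr(Ztr, "scale"))
      fit <- e1071::svm(Ztr, y[tr], kernel = kernel, cost = C, scale = FALSE)
      pred <- stats::predict(fit, Zte)
      errs[k, f] <- mean(pred != y[te])
    }
  }
  mean_err <- rowMeans(errs)
  k_star <- which(mean_err == min(mean_err))[1L]
  curve <- data.frame(k = seq_len(p), mean_error = mean_err)
  curve[paste0("fold", seq_len(n_folds))] <- errs
  list(curve = curve, k_star = k_star, folds = fold)
}

#' Select the key features at the CV optimum and refit
#'
#' @param X Samples x features matrix.
#' @param y Binary labels.
#' @param curve Output of [cv_error_curve()].
#' @param ranking Named rank vector from [rfe_rank()].
#' @param kernel Kernel for the final refit.
#' @param C Soft-margin cost.
#' @return list(key_features, k_star, cv_error at k*, cv_accuracy,
#'   training_accuracy of the full-data refit).
#' @export
select_key_features <- function(X, y, curve, ranking,
                                kernel = c("linear", "radial"), C = 1) {
  kernel <- match.arg(kernel)
  y <- factor(y)
  k_star <- curve$k_star
  feats <- names(sort(ranking))[seq_len(k_star)]
  Z <- .standardize(X[, feats, drop = FALSE])
  fit <- e1071::svm(Z, y, kernel = kernel, cost = C, scale = FALSE)
  acc <- mean(stats::predict(fit, Z) == y)
  list(key_features = sort(feats),
       k_star = k_star,
       cv_error = curve$curve$mean_error[k_star],
       cv_accuracy = 1 - curve$curve$mean_error[k_star],
       training_accuracy = acc)
}
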