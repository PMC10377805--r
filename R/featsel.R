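# Feature selection on the [0, 4.2] ppm feature grid: a floating
# sequential forward wrapper around LDA (the reference path) plus chi-square,
# ANOVA-F (k-best), lasso and Boruta baselines, all post-processed by
# Pearson-correlation redundancy dropping that discards the higher-ppm
# member of each correlated pair.

#' Drop mutually correlated features
#'
#' For every candidate pair whose Pearson correlation exceeds the threshold,
#' the higher-ppm (left, lower grid index) member is discarded; the scan is
#' iterated until no pair exceeds the threshold. Constant features have
#' undefined correlation and are kept.
#'
#' @param X Feature matrix (columns = full feature grid).
#' @param candidate_indices Column indices under consideration.
#' @param threshold Correlation threshold, strict (> keeps at equality);
#'   default 0.80.
#' @param ppm ppm value of each grid column (default: the clinical grid).
#' @return Retained indices (original order of \code{candidate_indices}).
#' @export
drop_correlated <- function(X, candidate_indices, threshold = 0.80,
                            ppm = feature_ppm()) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  retained <- as.integer(candidate_indices)
  repeat {
    if (length(retained) < 2L) break
    C <- suppressWarnings(stats::cor(X[, retained, drop = FALSE]))
    C[is.na(C)] <- 0
    diag(C) <- 0
    over <- which(C > threshold, arr.ind = TRUE)
    if (nrow(over) == 0L) break
    # among offending pairs, drop the member with the highest ppm first
    members <- unique(as.vector(over))
    drop_pos <- members[which.max(ppm[retained[members]])]
    retained <- retained[-drop_pos]
  }
  retained
}

# Stratified fold assignment, deterministic given seed.
stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Cross-validated balanced accuracy of an LDA wrapper
#'
#' The selection criterion used inside SFFS: stratified k-fold
#' cross-validation of \code{\link{lda_fit}} on the given feature subset,
#' scored by balanced accuracy (1 - BER).
#'
#' @param X,y Data and labels.
#' @param subset Feature column indices.
#' @param folds Fold assignment from the same seed for every evaluated
#'   subset (so subsets are compared on identical splits).
#' @return Balanced accuracy in [0, 1].
#' @export
cv_criterion <- function(X, y, subset, folds) {
  classes <- sort(unique(as.character(y)))
  pred <- character(length(y))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    model <- lda_fit(X[tr, subset, drop = FALSE], y[tr])
    sc <- lda_predict(model, X[!tr, subset, drop = FALSE])
    pred[!tr] <- score_labels(sc)
  }
  1 - ber(y, pred, classes)
}

#' Sequential floating forward feature selection (SFFS)
#'
#' Greedy forward addition of the feature that maximizes the
#' cross-validated balanced accuracy of an LDA wrapper, followed after each
#' addition by conditional backward removals that are accepted only when
#' they improve the best criterion recorded for the smaller subset size.
#' Stops when the subset reaches size \code{k}. Redundant candidates are
#' removed from the pool first (see \code{\link{drop_correlated}}).
#'
#' @param X Feature matrix.
#' @param y Labels (>= 2 classes).
#' @param k Target number of features (reference configurations: 8 for the
#'   4-class task, 9 for the 3-class task).
#' @param cv_folds Stratified folds of the wrapper (default 5).
#' @param seed Seed fixing the fold assignment.
#' @param candidates Candidate pool (default: all columns).
#' @param cor_threshold Redundancy threshold applied to the pool; NULL
#'   disables.
#' @return A \code{feature_set}: list with \code{indices}, \code{ppm},
#'   \code{method}, \code{k}, \code{cv_score}.
#' @export
sffs_select <- function(X, y, k, cv_folds = 5L, seed = 1L,
                        candidates = seq_len(ncol(X)),
                        cor_threshold = 0.80) {
  if (k < 1L) stop("k must be >= 1")
  if (k > ncol(X)) stop("k exceeds the feature count")
  y <- as.character(y)
  if (length(unique(y)) < 2L) stop("need >= 2 classes")
  if (min(table(y)) < cv_folds)
    stop("a class has fewer members than cv_folds")
  if (!is.null(cor_threshold))
    candidates <- drop_correlated(X, candidates, cor_threshold)
  folds <- stratified_folds(y, cv_folds, seed)
  crit <- function(subset) cv_criterion(X, y, subset, folds)
  selected <- integer(0)
  best_by_size <- rep(-Inf, k)
  while (length(selected) < k) {
    pool <- setdiff(candidates, selected)
    scores <- vapply(pool, function(f) crit(c(selected, f)), numeric(1))
    add <- pool[which.max(scores)]
    selected <- c(selected, add)
    best_by_size[length(selected)] <- max(best_by_size[length(selected)],
                                          max(scores))
    # conditional backward: remove features while that improves the best
    # known criterion at the smaller size
    while (length(selected) > 2L) {
      sub_scores <- vapply(seq_along(selected), function(j)
        crit(selected[-j]), numeric(1))
      jbest <- which.max(sub_scores)
      size <- length(selected) - 1L
      if (sub_scores[jbest] > best_by_size[size] + 1e-12 &&
          selected[jbest] != add) {
        selected <- selected[-jbest]
        best_by_size[size] <- sub_scores[jbest]
      } else break
    }
  }
  structure(list(indices = selected, ppm = feature_ppm()[selected],
                 method = "sffs", k = k, cv_score = crit(selected)),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %s, %d feature(s), cv_score %.3f\n",
              x$method, length(x$indices),
              if (is.null(x$cv_score)) NA else x$cv_score))
  cat("  ppm:", paste(sprintf("%.2f", x$ppm), collapse = " "), "\n")
  invisible(x)
}

# chi-square statistic per feature, scikit-learn convention: observed counts
# are sums of the (non-negative) feature per class, expected from class
# frequencies
chi2_stats <- function(X, y) {
  Xn <- sweep(X, 2, pmin(apply(X, 2, min), 0))  # min-shift to nonneg
  classes <- sort(unique(y))
  obs <- t(vapply(classes, function(cl)
    colSums(Xn[y == cl, , drop = FALSE]), numeric(ncol(X))))
  tot <- colSums(obs)
  pcls <- as.numeric(table(factor(y, classes))) / length(y)
  expd <- outer(pcls, tot)
  stat <- colSums((obs - expd)^2 / pmax(expd, 1e-12))
  stat[tot <= 0] <- 0
  stat
}

# one-way ANOVA F statistic per feature
anova_f_stats <- function(X, y) {
  classes <- sort(unique(y))
  n <- nrow(X); K <- length(classes)
  gm <- colMeans(X)
  ssb <- numeric(ncol(X)); ssw <- numeric(ncol(X))
  for (cl in classes) {
    Xc <- X[y == cl, , drop = FALSE]
    m <- colMeans(Xc)
    ssb <- ssb + nrow(Xc) * (m - gm)^2
    ssw <- ssw + colSums(sweep(Xc, 2, m)^2)
  }
  (ssb / (K - 1)) / pmax(ssw / (n - K), 1e-24)
}

#' Boruta feature selection
#'
#' All-relevant selection against shadow features: each iteration appends a
#' column-permuted copy of the data, fits a random forest, and counts a
#' "hit" for every real feature whose importance exceeds the best shadow
#' importance. Features with significantly more hits than the binomial(iter,
#' 0.5) null (one-sided, level \code{alpha}) are confirmed.
#'
#' @param X,y Data and labels.
#' @param n_iter Iterations (default 100).
#' @param alpha Confirmation level (default 0.05).
#' @param n_trees Forest size per iteration (default 500; reduce for quick
#'   runs).
#' @param seed Seed.
#' @return List with \code{confirmed} (indices ranked by mean importance),
#'   \code{hits}, \code{mean_importance}.
#' @export
boruta_select <- function(X, y, n_iter = 100L, alpha = 0.05,
                          n_trees = 500L, seed = 1L) {
  X <- as.matrix(X)
  p <- ncol(X)
  set.seed(seed)
  iter_seeds <- sample.int(.Machine$integer.max, n_iter)
  hits <- numeric(p)
  imp_sum <- numeric(p)
  for (it in seq_len(n_iter)) {
    set.seed(iter_seeds[it])
    shadow <- apply(X, 2, sample)
    Xa <- cbind(X, shadow)
    fit <- rf_fit(Xa, y, n_trees = n_trees, seed = iter_seeds[it])
    imp <- fit$importance
    best_shadow <- max(imp[(p + 1):(2 * p)])
    hits <- hits + (imp[1:p] > best_shadow)
    imp_sum <- imp_sum + imp[1:p]
  }
  pval <- stats::pbinom(hits - 1, n_iter, 0.5, lower.tail = FALSE)
  confirmed <- which(pval < alpha)
  confirmed <- confirmed[order(imp_sum[confirmed], decreasing = TRUE)]
  list(confirmed = confirmed, hits = hits, mean_importance = imp_sum / n_iter)
}

#' Rank features by a filter/embedded/wrapper baseline
#'
#' @param X Feature matrix.
#' @param y Labels.
#' @param method \code{"chi"} (chi-square on min-shifted features),
#'   \code{"kbest"} (one-way ANOVA F), \code{"lasso"} (one-vs-rest
#'   L1-penalized logistic regression; features ranked by largest absolute
#'   coefficient across classes, only nonzero ones eligible) or
#'   \code{"boruta"} (shadow-feature random forest).
#' @param k Number of features requested.
#' @param params Method parameters (e.g. \code{n_iter}, \code{n_trees} for
#'   boruta).
#' @param cor_threshold Redundancy threshold applied to the ranked set
#'   (default 0.80; Boruta is typically swept over 0.5..0.9).
#' @param seed Seed.
#' @return A \code{feature_set}; may hold fewer than \code{k} features for
#'   lasso/boruta.
#' @export
rank_features <- function(X, y, method = c("chi", "kbest", "lasso", "boruta"),
                          k, params = list(), cor_threshold = 0.80,
                          seed = 1L) {
  method <- match.arg(method)
  X <- as.matrix(X)
  y <- as.character(y)
  ranked <- switch(method,
    chi = order(chi2_stats(X, y), decreasing = TRUE),
    kbest = order(anova_f_stats(X, y), decreasing = TRUE),
    lasso = lasso_rank(X, y, k),
    boruta = do.call(boruta_select,
                     c(list(X = X, y = y, seed = seed), params))$confirmed)
  top <- utils::head(ranked, k)
  if (!is.null(cor_threshold) && length(top) > 1L)
    top <- drop_correlated(X, top, cor_threshold)
  structure(list(indices = top, ppm = feature_ppm()[top], method = method,
                 k = k, cv_score = NA_real_),
            class = "feature_set")
}

# one-vs-rest L1 logistic path via glmnet; eligible = nonzero at the first
# lambda where at least k distinct features are active
lasso_rank <- function(X, y, k) {
  classes <- sort(unique(y))
  p <- ncol(X)
  coef_by_lambda <- list()
  fits <- lapply(classes, function(cl)
    glmnet::glmnet(X, as.integer(y == cl), family = "binomial", alpha = 1,
                   standardize = TRUE, nlambda = 60))
  lambdas <- sort(unique(unlist(lapply(fits, function(f) f$lambda))),
                  decreasing = TRUE)
  best <- NULL
  for (lam in lambdas) {
    cmax <- numeric(p)
    for (f in fits) {
      b <- abs(as.numeric(stats::coef(f, s = lam, exact = FALSE))[-1])
      cmax <- pmax(cmax, b)
    }
    active <- which(cmax > 0)
    best <- cmax
    if (length(active) >= k) break
  }
  active <- which(best > 0)
  active[order(best[active], decreasing = TRUE)]
}
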