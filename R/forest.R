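# A compact random forest (CART trees, Gini impurity, per-split feature
# subsampling, bootstrap bagging) with impurity-based variable importance.
# Implemented in-package because the evaluation contract only needs per-class
# scores and deterministic seeding; it is a baseline, not the reference
# classifier.

best_split <- function(X, y, K, features, min_node) {
  n <- length(y)
  best <- list(gain = -Inf)
  counts_total <- tabulate(y, K)
  gini_parent <- 1 - sum((counts_total / n)^2)
  for (f in features) {
    xf <- X[, f]
    ord <- order(xf)
    ys <- y[ord]
    xs <- xf[ord]
    left <- matrix(0, n, K)
    left[cbind(seq_len(n), ys)] <- 1
    left <- apply(left, 2, cumsum)
    i <- seq_len(n - 1L)
    valid <- xs[i] < xs[i + 1L] & i >= min_node & (n - i) >= min_node
    if (!any(valid)) next
    i <- i[valid]
    nl <- i; nr <- n - i
    gl <- 1 - rowSums((left[i, , drop = FALSE] / nl)^2)
    gr <- 1 - rowSums((sweep(-left[i, , drop = FALSE], 2, counts_total, "+") / nr)^2)
    imp <- (nl * gl + nr * gr) / n
    j <- which.min(imp)
    gain <- gini_parent - imp[j]
    if (gain > best$gain) {
      best <- list(gain = gain, feature = f,
                   threshold = (xs[i[j]] + xs[i[j] + 1L]) / 2)
    }
  }
  if (!is.finite(best$gain) || best$gain <= 1e-12) NULL else best
}

grow_tree <- function(X, y, K, mtry, max_depth, min_node, importance) {
  build <- function(idx, depth) {
    yy <- y[idx]
    probs <- tabulate(yy, K) / length(yy)
    if (depth >= max_depth || length(idx) < 2L * min_node ||
        length(unique(yy)) == 1L)
      return(list(leaf = TRUE, probs = probs))
    feats <- sample.int(ncol(X), min(mtry, ncol(X)))
    sp <- best_split(X[idx, , drop = FALSE], yy, K, feats, min_node)
    if (is.null(sp)) return(list(leaf = TRUE, probs = probs))
    importance[sp$feature] <<- importance[sp$feature] +
      sp$gain * length(idx)
    go_left <- X[idx, sp$feature] <= sp$threshold
    list(leaf = FALSE, feature = sp$feature, threshold = sp$threshold,
         left = build(idx[go_left], depth + 1L),
         right = build(idx[!go_left], depth + 1L))
  }
  tree <- build(seq_len(nrow(X)), 0L)
  list(tree = tree, importance = importance)
}

predict_tree <- function(node, x) {
  while (!node$leaf)
    node <- if (x[node$feature] <= node$threshold) node$left else node$right
  node$probs
}

#' Fit a random forest classifier
#'
#' @param X Numeric matrix (samples x features).
#' @param y Factor or character class labels.
#' @param n_trees Number of bagged trees.
#' @param mtry Features tried per split (default \code{sqrt(p)}).
#' @param max_depth,min_node Tree size controls.
#' @param seed Integer seed; identical seeds give identical forests.
#' @return An \code{rf_model} with \code{importance} (impurity decrease per
#'   feature) usable with \code{\link{predict_scores}}.
#' @export
rf_fit <- function(X, y, n_trees = 200L, mtry = NULL, max_depth = 10L,
                   min_node = 2L, seed = 1L) {
  X <- as.matrix(X)
  classes <- sort(unique(as.character(y)))
  yi <- match(as.character(y), classes)
  K <- length(classes)
  mtry <- mtry %||% max(1L, floor(sqrt(ncol(X))))
  set.seed(seed)
  importance <- numeric(ncol(X))
  trees <- vector("list", n_trees)
  n <- nrow(X)
  for (b in seq_len(n_trees)) {
    idx <- sample.int(n, n, replace = TRUE)
    res <- grow_tree(X[idx, , drop = FALSE], yi[idx], K, mtry, max_depth,
                     min_node, importance)
    trees[[b]] <- res$tree
    importance <- res$importance
  }
  structure(list(trees = trees, classes = classes,
                 importance = importance / n_trees, mtry = mtry),
            class = c("rf_model", "nosomap_classifier"))
}

#' @export
predict_scores.rf_model <- function(model, X, ...) {
  X <- as.matrix(X)
  probs <- matrix(0, nrow(X), length(model$classes))
  for (tr in model$trees)
    probs <- probs + t(apply(X, 1, function(x) predict_tree(tr, x)))
  probs <- probs / length(model$trees)
  colnames(probs) <- model$classes
  probs
}
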