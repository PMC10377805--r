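# Classification of voxel spectra: LDA is the reference classifier (the one
# used for the nosological maps); random forest and linear SVM are baselines
# exposed through the same scoring interface. Evaluation uses the balanced
# error rate (BER) and per-class one-vs-rest AUC, repeated over stratified
# bootstrap resamples of the training set.

#' Classification task definitions
#'
#' The 4-class task is mm vs lgg vs agg vs no; the 3-class task drops lgg.
#' The superclass map sends gb and me to agg.
#'
#' @param name \code{"four_class"} or \code{"three_class"}.
#' @return List with \code{name}, ordered \code{classes} and
#'   \code{superclass} map.
#' @export
class_task <- function(name = c("four_class", "three_class")) {
  name <- match.arg(name)
  classes <- if (name == "four_class") c("mm", "lgg", "agg", "no")
             else c("mm", "agg", "no")
  list(name = name, classes = classes,
       superclass = c(gb = "agg", me = "agg"))
}

#' Map fine diagnostic labels onto a task's classes
#'
#' gb and me become agg; labels not in the task (e.g. lgg in the 3-class
#' task) become NA and should be excluded by the caller.
#'
#' @param labels Character vector of fine labels.
#' @param task A \code{\link{class_task}}.
#' @return Character vector of task classes (NA where unmapped).
#' @export
map_to_task <- function(labels, task) {
  out <- as.character(labels)
  sup <- task$superclass
  hit <- out %in% names(sup)
  out[hit] <- sup[out[hit]]
  out[!out %in% task$classes] <- NA_character_
  out
}

#' Generic per-class score prediction
#'
#' All classifiers in the package implement this: an n x K matrix of
#' non-negative per-class scores (posterior probabilities for LDA; vote
#' fractions for the forest; normalized decision values for the SVM), with
#' class names as column names.
#'
#' @param model A fitted classifier.
#' @param X Matrix of samples on the model's feature columns.
#' @param ... Unused.
#' @export
predict_scores <- function(model, X, ...) UseMethod("predict_scores")

#' Winning labels from per-class scores
#'
#' @param scores Matrix from \code{\link{predict_scores}}.
#' @return Character vector; ties broken by column order.
#' @export
score_labels <- function(scores) {
  colnames(scores)[max.col(scores, ties.method = "first")]
}

#' Fit a linear discriminant analysis classifier
#'
#' Class means with a pooled, ridge-regularized within-class covariance.
#' Posteriors are Gaussian: p(c | x) proportional to
#' prior_c * exp(-0.5 * (x - mu_c)' Sigma^-1 (x - mu_c)).
#'
#' @param X Numeric matrix (samples x features).
#' @param y Class labels (>= 2 classes, each with >= 2 samples).
#' @param priors Named prior vector (default: empirical frequencies); may be
#'   \code{"uniform"}.
#' @param ridge Ridge added to the covariance diagonal, as a fraction of the
#'   mean diagonal element (default 1e-6).
#' @return An \code{lda_model}.
#' @export
lda_fit <- function(X, y, priors = NULL, ridge = 1e-6) {
  X <- as.matrix(X)
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop("need at least 2 classes")
  counts <- table(factor(y, classes))
  if (any(counts < 2L)) stop("every class needs at least 2 samples")
  p <- ncol(X)
  means <- matrix(0, length(classes), p, dimnames = list(classes, colnames(X)))
  for (cl in classes)
    means[cl, ] <- colMeans(X[y == cl, , drop = FALSE])
  S <- matrix(0, p, p)
  for (cl in classes) {
    Xc <- sweep(X[y == cl, , drop = FALSE], 2, means[cl, ])
    S <- S + crossprod(Xc)
  }
  S <- S / (nrow(X) - length(classes))
  eps <- ridge * mean(diag(S))
  if (eps <= 0) eps <- ridge
  S <- S + diag(eps, p)
  pri <- if (identical(priors, "uniform")) {
    stats::setNames(rep(1 / length(classes), length(classes)), classes)
  } else if (is.null(priors)) {
    as.numeric(counts) / length(y)
  } else priors[classes]
  pri <- pri / sum(pri)
  structure(list(classes = classes, means = means, cov = S,
                 cov_inv = solve(S), priors = stats::setNames(as.numeric(pri), classes),
                 features = colnames(X)),
            class = c("lda_model", "nosomap_classifier"))
}

#' Posterior probabilities from an LDA model
#'
#' @param model An \code{lda_model}.
#' @param X Matrix on the model's features.
#' @return n x K matrix of posteriors, rows summing to 1.
#' @export
lda_predict <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != ncol(model$means)) stop("feature dimension mismatch")
  K <- length(model$classes)
  logd <- matrix(0, nrow(X), K)
  for (k in seq_len(K)) {
    D <- sweep(X, 2, model$means[k, ])
    logd[, k] <- log(model$priors[k]) - 0.5 * rowSums((D %*% model$cov_inv) * D)
  }
  logd <- logd - apply(logd, 1, max)
  post <- exp(logd)
  post <- post / rowSums(post)
  colnames(post) <- model$classes
  post
}

#' @export
predict_scores.lda_model <- function(model, X, ...) lda_predict(model, X)

#' Balanced error rate
#'
#' Mean over classes of the per-class misclassification fraction.
#'
#' @param y_true,y_pred Label vectors.
#' @param classes Classes to average over; each must occur in \code{y_true}.
#' @return BER in [0, 1].
#' @export
ber <- function(y_true, y_pred, classes = sort(unique(y_true))) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  errs <- vapply(classes, function(cl) {
    idx <- y_true == cl
    if (!any(idx)) stop("class absent from y_true: ", cl)
    mean(y_pred[idx] != cl)
  }, numeric(1))
  mean(errs)
}

#' One-vs-rest AUC
#'
#' Mann-Whitney AUC of the class score as a ranking statistic, ties counted
#' as 0.5.
#'
#' @param y_true Label vector.
#' @param scores Score vector for class \code{class_c} (higher = more
#'   likely).
#' @param class_c The positive class; must have at least one positive and
#'   one negative.
#' @return AUC in [0, 1].
#' @export
auc_ovr <- function(y_true, scores, class_c) {
  pos <- as.character(y_true) == class_c
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    stop("class ", class_c, " needs both positives and negatives")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

compute_metrics <- function(y_true, scores, classes) {
  labels <- score_labels(scores)
  aucs <- vapply(classes, function(cl)
    auc_ovr(y_true, scores[, cl], cl), numeric(1))
  list(ber = ber(y_true, labels, classes), auc = aucs)
}

fit_classifier <- function(X, y, classifier = "lda", params = list(),
                           seed = 1L) {
  switch(classifier,
    lda = do.call(lda_fit, c(list(X = X, y = y), params)),
    rf = do.call(rf_fit, c(list(X = X, y = y, seed = seed), params)),
    svm = do.call(svm_fit, c(list(X = X, y = y), params)),
    stop("unknown classifier: ", classifier))
}

#' Bootstrap evaluation of a classifier configuration
#'
#' Repeats \code{n_reps} times: stratified resample of the training set with
#' replacement (class counts preserved, so no class can vanish), refit,
#' compute BER and per-class AUC on the in-bag resampled training data and
#' on the fixed test set. Feature selection is done once, before this
#' function; the bootstrap refits only the classifier.
#'
#' @param train,test Lists with \code{X} (matrix on the selected features)
#'   and \code{y} (task labels).
#' @param classifier \code{"lda"}, \code{"rf"} or \code{"svm"}.
#' @param params Extra arguments for the classifier's fit function.
#' @param n_reps Number of bootstrap replicates (reference protocol: 1000).
#' @param seed Integer seed.
#' @param resample Set FALSE to refit on the unresampled training set
#'   (useful for smoke tests; mean = min = max then holds trivially).
#' @return A \code{metrics_summary}: per-replicate matrices and
#'   mean/min/max aggregates of BER_train, BER_test, per-class AUC_train
#'   and AUC_test, plus the ratio summaries used for model selection.
#' @export
bootstrap_evaluate <- function(train, test, classifier = "lda",
                               params = list(), n_reps = 1000L, seed = 1L,
                               resample = TRUE) {
  classes <- sort(unique(as.character(train$y)))
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_reps)
  idx_by_class <- split(seq_along(train$y), as.character(train$y))
  ber_tr <- ber_te <- numeric(n_reps)
  auc_tr <- auc_te <- matrix(NA_real_, n_reps, length(classes),
                             dimnames = list(NULL, classes))
  for (r in seq_len(n_reps)) {
    set.seed(rep_seeds[r])
    idx <- if (resample) {
      unlist(lapply(idx_by_class, function(ii)
        ii[sample.int(length(ii), length(ii), replace = TRUE)]),
        use.names = FALSE)
    } else seq_along(train$y)
    Xb <- train$X[idx, , drop = FALSE]; yb <- train$y[idx]
    model <- fit_classifier(Xb, yb, classifier, params, seed = rep_seeds[r])
    mtr <- compute_metrics(yb, predict_scores(model, Xb), classes)
    mte <- compute_metrics(test$y, predict_scores(model, test$X), classes)
    ber_tr[r] <- mtr$ber; ber_te[r] <- mte$ber
    auc_tr[r, ] <- mtr$auc; auc_te[r, ] <- mte$auc
  }
  agg <- function(x) c(mean = mean(x), min = min(x), max = max(x))
  structure(list(
    classes = classes, n_reps = n_reps, classifier = classifier,
    ber_train = ber_tr, ber_test = ber_te,
    auc_train = auc_tr, auc_test = auc_te,
    summary = list(
      ber_train = agg(ber_tr), ber_test = agg(ber_te),
      auc_train = apply(auc_tr, 2, agg), auc_test = apply(auc_te, 2, agg),
      auc_ratio = mean(colMeans(auc_te) / colMeans(auc_tr)),
      ber_ratio = mean(ber_te) / max(mean(ber_tr), 1e-12))),
    class = "metrics_summary")
}

#' @export
print.metrics_summary <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<metrics_summary> %s, %d replicates\n", x$classifier, x$n_reps))
  cat(sprintf("  BER  train %.3f / test %.3f (mean)\n",
              s$ber_train["mean"], s$ber_test["mean"]))
  cat(sprintf("  AUC  test mean %.3f, test/train ratio %.3f\n",
              mean(s$auc_test["mean", ]), s$auc_ratio))
  invisible(x)
}

#' Select the best classifier configuration
#'
#' Lexicographic ranking mirroring the published criterion: (1) smallest
#' mean over classes of |1 - AUC_test/AUC_train|; (2) largest mean AUC_test;
#' (3) smallest mean BER_test; remaining ties broken by candidate order.
#'
#' @param candidates List of \code{metrics_summary} objects.
#' @param configs Optional parallel list of configuration descriptors to
#'   return alongside.
#' @return List with \code{index}, \code{metrics} and (if given)
#'   \code{config}.
#' @export
select_best_model <- function(candidates, configs = NULL) {
  if (length(candidates) == 0L) stop("empty candidate list")
  crit <- t(vapply(candidates, function(m) {
    ratio_dev <- mean(abs(1 - colMeans(m$auc_test) / colMeans(m$auc_train)))
    c(ratio_dev, -mean(m$auc_test), m$summary$ber_test["mean"])
  }, numeric(3)))
  best <- order(crit[, 1], crit[, 2], crit[, 3])[1]
  out <- list(index = best, metrics = candidates[[best]])
  if (!is.null(configs)) out$config <- configs[[best]]
  out
}

#' Linear SVM baseline (one-vs-rest, squared hinge)
#'
#' L2-regularized linear classifier trained by quasi-Newton minimization of
#' the squared hinge loss, one binary problem per class. Deterministic.
#'
#' @param X Matrix (samples x features).
#' @param y Class labels.
#' @param cost Inverse regularization strength.
#' @return An \code{svm_model} usable with \code{\link{predict_scores}}.
#' @export
svm_fit <- function(X, y, cost = 1) {
  X <- as.matrix(X)
  y <- as.character(y)
  classes <- sort(unique(y))
  mu <- colMeans(X); sdv <- pmax(apply(X, 2, stats::sd), 1e-12)
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  p <- ncol(Xs); n <- nrow(Xs)
  lambda <- 1 / (cost * n)
  weights <- matrix(0, p + 1, length(classes),
                    dimnames = list(NULL, classes))
  for (cl in classes) {
    yy <- ifelse(y == cl, 1, -1)
    obj <- function(w) {
      f <- Xs %*% w[1:p] + w[p + 1]
      m <- pmax(0, 1 - yy * f)
      lambda / 2 * sum(w[1:p]^2) + mean(m^2)
    }
    grad <- function(w) {
      f <- Xs %*% w[1:p] + w[p + 1]
      m <- pmax(0, 1 - yy * f)
      gw <- lambda * w[1:p] - 2 / n * t(Xs) %*% (m * yy)
      c(as.numeric(gw), -2 / n * sum(m * yy))
    }
    fit <- stats::optim(numeric(p + 1), obj, grad, method = "L-BFGS-B",
                        control = list(maxit = 200))
    weights[, cl] <- fit$par
  }
  structure(list(classes = classes, weights = weights, center = mu,
                 scale = sdv),
            class = c("svm_model", "nosomap_classifier"))
}

#' @export
predict_scores.svm_model <- function(model, X, ...) {
  X <- as.matrix(X)
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  p <- ncol(Xs)
  f <- Xs %*% model$weights[1:p, , drop = FALSE]
  f <- sweep(f, 2, model$weights[p + 1, ], "+")
  # map decision values to (0, 1) scores; ranking (AUC) is unaffected
  sc <- 1 / (1 + exp(-f))
  sc <- sc / pmax(rowSums(sc), 1e-12)
  colnames(sc) <- model$classes
  sc
}

#' Baseline classifiers with the common scoring interface
#'
#' @param X,y Training data.
#' @param method \code{"rf"} or \code{"svm"}.
#' @param params Passed to the underlying fit.
#' @param seed Seed (random forest only).
#' @return A fitted model answering \code{\link{predict_scores}}.
#' @export
baseline_classifier <- function(X, y, method = c("rf", "svm"),
                                params = list(), seed = 1L) {
  method <- match.arg(method)
  fit_classifier(X, y, method, params, seed = seed)
}
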