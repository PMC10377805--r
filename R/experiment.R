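# Experiment grid runner: feature-selection methods x feature counts x
# classifiers, each evaluated by bootstrap BER/AUC on the training set and a
# fixed test set, producing the long table from which the per-method BER
# matrices (train and test blocks) are built.

#' Run the feature-selection x classifier experiment grid
#'
#' For every combination of feature-selection method, requested feature
#' count and classifier: select features on the training set, evaluate with
#' \code{\link{bootstrap_evaluate}}, and record the aggregate metrics. The
#' reference study swept 3..20 features; counts outside that range are
#' rejected.
#'
#' @param train,test Lists with \code{X} (full feature grid) and \code{y}
#'   (task labels).
#' @param methods Subset of \code{c("sffs", "chi", "kbest", "lasso",
#'   "boruta")}.
#' @param ks Feature counts, all within 3..20.
#' @param classifiers Subset of \code{c("lda", "rf", "svm")}.
#' @param n_reps Bootstrap replicates per cell.
#' @param seed Seed.
#' @param fs_params Named list of per-method parameter lists (e.g.
#'   \code{list(boruta = list(n_trees = 50, n_iter = 20))}).
#' @param clf_params Named list of per-classifier parameter lists (e.g.
#'   \code{list(rf = list(n_trees = 60))}).
#' @return List with \code{results} (long data.frame: method, k, classifier,
#'   ber_train_mean/min/max, ber_test_mean/min/max, auc_train_mean,
#'   auc_test_mean, auc_ratio), \code{metrics} (the raw
#'   \code{metrics_summary} objects) and \code{features} (selected sets).
#' @export
run_experiment_grid <- function(train, test, methods = c("sffs", "kbest"),
                                ks = 3:10, classifiers = c("lda", "rf", "svm"),
                                n_reps = 50L, seed = 1L, fs_params = list(),
                                clf_params = list()) {
  if (any(ks < 3L | ks > 20L))
    stop("feature counts must lie in 3..20")
  bad <- setdiff(methods, c("sffs", "chi", "kbest", "lasso", "boruta"))
  if (length(bad)) stop("unknown feature selection method(s): ",
                        paste(bad, collapse = ", "))
  rows <- list(); metrics <- list(); featsets <- list()
  for (m in methods) for (k in ks) {
    fs <- if (m == "sffs") {
      sffs_select(train$X, train$y, k = k, seed = seed)
    } else {
      do.call(rank_features,
              c(list(X = train$X, y = train$y, method = m, k = k,
                     seed = seed),
                list(params = fs_params[[m]] %||% list())))
    }
    idx <- fs$indices
    if (length(idx) < 2L) next
    for (clf in classifiers) {
      ms <- bootstrap_evaluate(
        list(X = train$X[, idx, drop = FALSE], y = train$y),
        list(X = test$X[, idx, drop = FALSE], y = test$y),
        classifier = clf, params = clf_params[[clf]] %||% list(),
        n_reps = n_reps, seed = seed)
      key <- paste(m, k, clf, sep = "_")
      metrics[[key]] <- ms
      featsets[[paste(m, k, sep = "_")]] <- fs
      s <- ms$summary
      rows[[key]] <- data.frame(
        method = m, k = k, classifier = clf,
        ber_train_mean = s$ber_train["mean"], ber_train_min = s$ber_train["min"],
        ber_train_max = s$ber_train["max"],
        ber_test_mean = s$ber_test["mean"], ber_test_min = s$ber_test["min"],
        ber_test_max = s$ber_test["max"],
        auc_train_mean = mean(s$auc_train["mean", ]),
        auc_test_mean = mean(s$auc_test["mean", ]),
        auc_ratio = s$auc_ratio, row.names = NULL)
    }
  }
  list(results = do.call(rbind, rows), metrics = metrics,
       features = featsets)
}
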