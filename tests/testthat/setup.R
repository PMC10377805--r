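# Shared fixtures, built once: a 50-per-class synthetic single-voxel
# training set processed through the full pipeline, the SFFS(k = 8) feature
# set and the LDA model trained on it. Several test files (and the
# end-to-end acceptance criteria) reuse these to stay inside the time
# budget.

fx <- new.env()

fx$task <- class_task("four_class")
fx$profiles <- build_class_profiles()
fx$sv <- simulate_sv_dataset(c(no = 50, mm = 50, agg = 50, lgg = 50),
                             seed = 101)
fx$svp <- process_fids(fx$sv$fids)
fx$y <- map_to_task(fx$sv$labels, fx$task)
fx$fs <- sffs_select(fx$svp$features, fx$y, k = 8, seed = 101)
fx$model <- lda_fit(fx$svp$features[, fx$fs$indices], fx$y)
fx$templates <- nosomap:::class_templates()

fx$classify_phantom <- function(ph, qc = NULL) {
  mvp <- process_fids(ph$fids)
  if (is.null(qc)) qc <- qc_screen(mvp$canonical, mask = ph$truth)
  feats <- mvp$features[, fx$fs$indices, drop = FALSE]
  map <- classify_grid(fx$model, feats, qc = qc, task = fx$task,
                       dims = ph$dims)
  list(map = map, report = grid_metrics(map, ph$truth, ph$case_class,
                                        scores = predict_scores(fx$model, feats)),
       mvp = mvp, qc = qc, feats = feats)
}
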