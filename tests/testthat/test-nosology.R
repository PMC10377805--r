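# Nosological maps and their evaluation scores.

test_that("STI matches its definition and the 0.50 success rule", {
  task <- class_task("four_class")
  truth <- c(rep("solid", 10), rep("normal", 5))
  # 2 solid voxels excluded, 6 of the remaining 8 correct
  cls <- c(rep("agg", 6), rep("no", 2), "agg", "agg", rep("no", 5))
  excl <- c(rep(FALSE, 8), TRUE, TRUE, rep(FALSE, 5))
  m <- toy_map(cls, excluded = excl, task = task)
  s <- sti(m, truth, "gb")
  expect_equal(s$sti, 0.75)
  expect_true(s$success)
  # all solid correct -> 1.0
  perfect <- toy_map(c(rep("agg", 10), rep("no", 5)), task = task)
  expect_equal(sti(perfect, truth, "gb")$sti, 1.0)
  # exactly 0.5 is not a success (threshold is strict)
  half <- toy_map(c(rep("agg", 5), rep("mm", 5), rep("no", 5)), task = task)
  expect_false(sti(half, truth, "gb")$success)
  all_excl <- toy_map(rep("no", 15), excluded = c(rep(TRUE, 10), rep(FALSE, 5)))
  expect_error(sti(all_excl, truth, "gb"), "no solid")
})

test_that("Dice matches its set formula, with NA for empty-empty", {
  truth <- c(rep("solid", 5), rep("normal", 7))
  # |A| = 5 solid, |B| = 4 predicted agg, overlap 3 -> 6/9
  cls <- c(rep("agg", 3), "no", "no", "agg", rep("no", 6))
  m <- toy_map(cls)
  expect_equal(dice(m, truth, "solid", "agg"), 6 / 9)
  expect_equal(dice(toy_map(c(rep("agg", 5), rep("no", 7))), truth,
                    "solid", "agg"), 1.0)
  expect_equal(dice(toy_map(rep("no", 12)), truth, "solid", "agg"), 0.0)
  expect_true(is.na(dice(m, truth, "abnormal", "lgg")))
})

test_that("classify_grid carries exclusions, posteriors and colors", {
  set.seed(31)
  X <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 4), 20))
  y <- rep(c("no", "agg"), each = 20)
  model <- lda_fit(X, y)
  qc <- data.frame(voxel = 1:40,
                   status = c("excluded_ventricle",
                              rep("kept", 38), "discarded_artifact"),
                   snr = 20, winning_source = NA)
  map <- classify_grid(model, X, qc = qc, task = class_task(),
                       dims = c(8, 5, 1))
  expect_true(map$voxels$excluded[1])
  expect_identical(map$voxels$reason[40], "discarded_artifact")
  expect_true(is.na(map$voxels$class[1]))
  expect_true(all(!is.na(map$voxels$class[2:39])))
  expect_true(all(map$voxels$posterior[2:39] >= 0.5 - 1e-9))
  # color assignment is the published one and a bijection on task classes
  expect_identical(map$colors[["no"]], "#0000FF")
  expect_identical(map$colors[["agg"]], "#FF0000")
  expect_identical(map$colors[["lgg"]], "#00B200")
  expect_identical(map$colors[["mm"]], "#FFD700")
  expect_false(anyDuplicated(map$colors) > 0)
  expect_error(classify_grid(model, X, qc = qc[1:5, ]), "does not match")
})

test_that("grid_metrics restricts BER/AUC to solid and normal voxels", {
  task <- class_task("four_class")
  truth <- c(rep("solid", 6), rep("abnormal", 4), rep("normal", 6))
  cls <- c(rep("agg", 6), rep("lgg", 4), rep("no", 6))
  m <- toy_map(cls, dims = c(4, 4, 1), task = task)
  scores <- matrix(0.01, 16, 4, dimnames = list(NULL, task$classes))
  scores[cbind(1:16, match(cls, task$classes))] <- 0.97
  rep_ <- grid_metrics(m, truth, "gb", scores = scores)
  expect_equal(rep_[rep_$metric == "ber", "value"], 0)
  aucs <- rep_[rep_$metric == "auc", ]
  expect_true(all(aucs$value == 1.0))
  # abnormal voxels never enter BER/AUC: mislabel them all, BER unchanged
  cls2 <- cls; cls2[7:10] <- "mm"
  m2 <- toy_map(cls2, dims = c(4, 4, 1), task = task)
  rep2 <- grid_metrics(m2, truth, "gb")
  expect_equal(rep2[rep2$metric == "ber", "value"], 0)
  expect_equal(rep_[rep_$metric == "sti", "value"], 1.0)
})

test_that("multi-slice phantoms report one entry per z slice", {
  task <- class_task("four_class")
  truth <- rep(c("solid", "normal"), each = 4, times = 2)
  cls <- rep(c("agg", "no"), each = 4, times = 2)
  m <- toy_map(cls, dims = c(2, 4, 2), task = task)
  rep_ <- grid_metrics(m, truth, "gb")
  expect_setequal(unique(rep_$slice), c("all", "1", "2"))
  sti_rows <- rep_[rep_$metric == "sti", ]
  expect_identical(nrow(sti_rows), 3L)
  expect_true(all(sti_rows$value == 1.0))
})

test_that("render_map produces deterministic RGBA with the display contract", {
  m <- toy_map(rep("no", 4), posteriors = rep(1, 4), dims = c(2, 2, 1))
  img <- render_map(m)
  expect_identical(dim(img), c(2L, 2L, 4L))
  for (x in 1:2) for (y in 1:2)
    expect_identical(img[x, y, ], c(0, 0, 1, 1))  # full-intensity blue
  # excluded voxel: black at alpha 0.5
  m2 <- toy_map(c("no", "no", "no", "no"), excluded = c(TRUE, rep(FALSE, 3)),
                dims = c(2, 2, 1))
  img2 <- render_map(m2)
  expect_identical(img2[1, 1, ], c(0, 0, 0, 0.5))
  # posterior scales intensity
  m3 <- toy_map(rep("agg", 4), posteriors = rep(0.5, 4), dims = c(2, 2, 1))
  expect_identical(render_map(m3)[1, 1, ], c(0.5, 0, 0, 1))
  expect_identical(render_map(m2), render_map(m2))
})
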