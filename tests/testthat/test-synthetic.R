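# Synthetic data module: class profiles, FID simulation, SV datasets, MV
# phantoms.

test_that("default class profiles follow the qualitative tumor patterns", {
  p <- build_class_profiles()
  expect_setequal(names(p), c("no", "gb", "me", "mm", "lgg"))
  amp <- function(prof, nm) {
    r <- Filter(function(x) x$name == nm, prof$resonances)[[1]]
    r$amplitude
  }
  # normal: NAA at 2.01 ppm is strictly the tallest resonance
  amps_no <- vapply(p$no$resonances, `[[`, numeric(1), "amplitude")
  expect_true(amp(p$no, "NAA") > max(amps_no[-which.max(amps_no)]))
  # aggressive: necrotic pattern, lipids at 0.9 and 1.28 above NAA
  for (cl in c("gb", "me")) {
    expect_gt(amp(p[[cl]], "Lip13"), amp(p[[cl]], "NAA"))
    expect_gt(amp(p[[cl]], "Lip09"), amp(p[[cl]], "NAA"))
  }
  # gb and me are distinct profiles (both map to agg downstream)
  expect_false(identical(p$gb$resonances, p$me$resonances))
})

test_that("profile config overrides work and degenerate profiles are legal", {
  p <- build_class_profiles(list(mm = list(
    amplitudes = c(NAA = 0, Cho = 0, Cr = 0))))
  amps <- vapply(p$mm$resonances, `[[`, numeric(1), "amplitude")
  expect_true(all(amps == 0))
  # all-zero profile simulates to pure noise without error
  f <- simulate_fid(p$mm, snr_target = 20, seed = 1)
  expect_s3_class(f, "mrs_fid")
  expect_error(build_class_profiles(list(tumorX = list())), "unknown class")
})

test_that("resonance and artifact_spec validate their invariants", {
  expect_error(resonance("X", 9.0, 0.05, 1), "outside")
  expect_error(resonance("X", 2.0, 0, 1), "linewidth")
  expect_error(resonance("X", 2.0, 0.05, -1), "amplitude")
  expect_error(artifact_spec(flip_prob = 1.5), "probabilities")
  expect_error(artifact_spec(shift_sd = -1), "shift_sd")
})

test_that("simulate_fid is deterministic and linear under flips", {
  p <- build_class_profiles()
  f1 <- simulate_fid(p$no, 25, seed = 11)
  f2 <- simulate_fid(p$no, 25, seed = 11)
  expect_identical(f1$samples, f2$samples)
  f3 <- simulate_fid(p$no, 25, seed = 12)
  expect_false(identical(f1$samples, f3$samples))
  # flip commutes with the FFT: spectrum of -FID = -spectrum of FID
  flipped <- f1; flipped$samples <- -f1$samples
  s1 <- fid_to_spectrum(f1); s2 <- fid_to_spectrum(flipped)
  expect_equal(s2$values, -s1$values, tolerance = 1e-12)
  expect_error(simulate_fid(p$no, -5, seed = 1), "snr_target")
})

test_that("snr_target maps monotonically onto the estimated SNR", {
  p <- build_class_profiles()
  hi <- lo <- numeric(5)
  for (i in 1:5) {
    f_hi <- simulate_fid(p$no, 40, seed = 100 + i)
    f_lo <- simulate_fid(p$no, 5, seed = 100 + i)
    hi[i] <- process_fid(f_hi, list(hlsvd = FALSE))$snr
    lo[i] <- process_fid(f_lo, list(hlsvd = FALSE))$snr
  }
  expect_true(all(hi > lo))
})

test_that("zero-noise, zero-artifact spectra peak at the profile centers", {
  p <- build_class_profiles(list(no = list(amplitude_cv = 0)))
  prof <- p$no
  prof$baseline_level <- 0
  f <- simulate_fid(prof, 1e7, seed = 1)
  res <- process_fid(f, list(hlsvd = FALSE, align = FALSE))
  ppm <- attr(res$features, "ppm")
  step <- 9.8 / 511
  for (target in c(2.01, 3.03, 3.21)) {
    win <- which(abs(ppm - target) <= 0.1)
    peak_ppm <- ppm[win[which.max(res$features[win])]]
    expect_lte(abs(peak_ppm - target), step + 1e-9)
  }
})

test_that("simulate_sv_dataset honors requested counts and the reference preset", {
  d <- simulate_sv_dataset(sv_class_counts(), seed = 3)
  expect_identical(table(factor(d$labels, c("no", "mm", "agg", "lgg"))),
                   table(factor(rep(c("no", "mm", "agg", "lgg"),
                                    c(22, 62, 123, 35)),
                                c("no", "mm", "agg", "lgg"))))
  # agg requests split between gb and me profiles
  expect_setequal(unique(d$fine_labels[d$labels == "agg"]), c("gb", "me"))
  d1 <- simulate_sv_dataset(c(no = 1, mm = 1, agg = 1, lgg = 1), seed = 5)
  expect_length(d1$fids, 4L)
  d2 <- simulate_sv_dataset(c(no = 2, lgg = 2), seed = 7)
  d3 <- simulate_sv_dataset(c(no = 2, lgg = 2), seed = 7)
  expect_identical(d2$fids[[1]]$samples, d3$fids[[1]]$samples)
  d4 <- simulate_sv_dataset(c(no = 2, lgg = 2), seed = 8)
  expect_false(identical(d2$fids[[1]]$samples, d4$fids[[1]]$samples))
  expect_error(simulate_sv_dataset(c()), "empty")
  expect_error(simulate_sv_dataset(c(xx = 3)), "unknown class")
})

test_that("phantom truth masks conserve voxel counts and geometry", {
  ph <- simulate_mv_phantom(c(18, 14, 1), "gb", seed = 2)
  expect_length(ph$truth, 252L)
  expect_length(ph$fids, 252L)
  expect_true(all(ph$truth %in% c("normal", "solid", "abnormal", "ventricle")))
  expect_gt(sum(ph$truth == "solid"), 0)
  ph_no <- simulate_mv_phantom(c(6, 5, 1), "no", seed = 2)
  expect_true(all(ph_no$truth == "normal"))
  expect_error(
    simulate_mv_phantom(c(6, 5, 1), "gb",
                        geometry = list(solid_center = c(6, 5),
                                        solid_radius = c(4, 4),
                                        abnormal_width = 1,
                                        ventricle = FALSE)),
    "exceeds dims")
})

test_that("artifact injection matches its specification in expectation", {
  art <- artifact_spec(flip_prob = 0.2)
  ph <- simulate_mv_phantom(c(25, 40, 1), "gb", artifacts = art, seed = 9,
                            geometry = phantom_geometry(c(25, 40, 1)))
  frac <- mean(vapply(ph$artifact_log, function(a) "flip" %in% a, logical(1)))
  # binomial 3 sigma band around 0.2 at n = 1000
  expect_gte(frac, 0.16)
  expect_lte(frac, 0.24)
})

test_that("phantoms are reproducible from (config, seed)", {
  a <- simulate_mv_phantom(c(8, 6, 1), "mm", seed = 4)
  b <- simulate_mv_phantom(c(8, 6, 1), "mm", seed = 4)
  expect_identical(a$truth, b$truth)
  expect_identical(a$fids[[17]]$samples, b$fids[[17]]$samples)
})
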