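# Spectral canonicalization: FFT, HLSVD water removal, resampling, flip and
# alignment correction, water-band zeroing, UL2 normalization, clinical-range
# extraction.

test_that("fid_to_spectrum places a pure tone at its chemical shift", {
  f <- toy_fid(list(c(2.01, 1, 1e-6)))
  sp <- fid_to_spectrum(f)
  expect_equal(sp$ppm[which.max(Mod(sp$values))], 2.01, tolerance = 0.01)
  z <- toy_fid(list())
  expect_true(all(Mod(fid_to_spectrum(z)$values) == 0))
})

test_that("fid_to_spectrum satisfies Parseval's identity without apodization", {
  f <- toy_fid(list(c(2.01, 1, 0.05), c(3.21, 0.5, 0.05)))
  sp <- fid_to_spectrum(f, apodization_hz = 0, zero_fill = 1L)
  e_time <- sum(Mod(f$samples)^2)
  e_freq <- sum(Mod(sp$values)^2) / f$n_points
  expect_equal(e_freq, e_time, tolerance = 1e-9)
})

test_that("hlsvd_filter removes in-region water and passes metabolites through", {
  water <- toy_fid(list(c(4.70, 5, 0.1)))
  hf <- hlsvd_filter(water)
  wi <- nosomap:::ppm_band_idx(4.31, 5.11)
  v0 <- resample_to_canonical(fid_to_spectrum(water))
  v1 <- resample_to_canonical(fid_to_spectrum(hf))
  expect_lte(max(abs(v1[wi])), 0.05 * max(abs(v0[wi])))
  # out-of-region component untouched within 2% relative RMS
  naa <- toy_fid(list(c(2.01, 1, 0.05)))
  hn <- hlsvd_filter(naa)
  rel <- sqrt(mean(Mod(hn$samples - naa$samples)^2)) /
    sqrt(mean(Mod(naa$samples)^2))
  expect_lte(rel, 0.02)
  expect_identical(nrow(attr(hn, "removed")), 0L)
  expect_error(hlsvd_filter(toy_fid(list(c(2, 1, 0.1)), n = 16)),
               "model_order")
})

test_that("resample_to_canonical is an interpolant on the fixed grid", {
  # input already on the canonical grid -> identity
  vals <- sin(seq_len(512) / 20)
  sp <- list(values = vals, ppm = canonical_ppm())
  expect_equal(resample_to_canonical(sp), vals, tolerance = 1e-12)
  # linear input reproduced exactly at every node
  ppm_in <- seq(-3, 7.5, length.out = 701)
  lin <- list(values = 2 * ppm_in + 1, ppm = ppm_in)
  out <- resample_to_canonical(lin)
  expect_length(out, 512L)
  expect_equal(out, 2 * canonical_ppm() + 1, tolerance = 1e-9)
  expect_equal(canonical_ppm()[1], 7.1)
  expect_equal(canonical_ppm()[512], -2.7)
  # insufficient coverage is an error, not extrapolation
  expect_error(resample_to_canonical(list(values = 1:10,
                                          ppm = seq(0, 4, length.out = 10))),
               "cover")
})

test_that("correct_flip detects inversions and fixes them involutively", {
  up <- toy_canonical(list(c(2.01, 30), c(3.21, 15)))
  r <- correct_flip(up)
  expect_false(r$flip_applied)
  expect_identical(r$values, up)
  rf <- correct_flip(-up)
  expect_true(rf$flip_applied)
  expect_identical(rf$values, up)
  # near-zero spectrum defaults to unflipped
  expect_false(correct_flip(toy_canonical(noise_amp = 1e-9))$flip_applied)
})

test_that("align_to_reference shifts onto the 2.01 bin with 3.21/3.03 fallback", {
  target_bin <- nearest_bin_pub(2.01)
  v <- toy_canonical()
  v[target_bin + 3L] <- 40   # NAA displaced +3 grid points
  al <- align_to_reference(v)
  expect_identical(al$shift_points, -3L)
  expect_equal(which.max(al$values), target_bin)
  # already aligned -> no shift
  v2 <- toy_canonical(list(c(2.01, 40)))
  expect_identical(align_to_reference(v2)$shift_points, 0L)
  # no NAA peak, clear Cho peak displaced -2 points -> aligned on 3.21
  cho_bin <- nearest_bin_pub(3.21)
  v3 <- toy_canonical()
  v3[cho_bin - 2L] <- 40
  al3 <- align_to_reference(v3)
  expect_identical(al3$shift_points, 2L)
  expect_equal(which.max(al3$values), cho_bin)
})

test_that("water-band zeroing is exact and idempotent", {
  v <- toy_canonical(list(c(4.7, 100), c(2.01, 30)))
  z <- zero_water_region(v)
  expect_identical(z[nearest_bin_pub(4.7)], 0)
  expect_true(all(z[nosomap:::water_zero_idx()] == 0))
  expect_identical(z[nearest_bin_pub(2.01)], v[nearest_bin_pub(2.01)])
  expect_identical(zero_water_region(z), z)
})

test_that("ul2_normalize scales to unit length and rejects dead spectra", {
  v <- c(3, 4, rep(0, 510))
  expect_equal(ul2_normalize(v), c(0.6, 0.8, rep(0, 510)))
  u <- ul2_normalize(toy_canonical(list(c(2.01, 10))))
  expect_equal(ul2_normalize(u), u, tolerance = 1e-12)
  expect_error(ul2_normalize(rep(0, 512)), "zero")
})

test_that("clinical-range extraction keeps zero-based indices 152..370", {
  idx <- nosomap:::clinical_idx()
  expect_identical(range(idx), c(153L, 371L))  # 1-based
  expect_length(idx, 219L)
  v <- toy_canonical(list(c(2.01, 30)))
  fe <- extract_clinical_range(v)
  expect_length(fe, 219L)
  expect_equal(sqrt(sum(fe^2)), 1, tolerance = 1e-9)
  # spectrum alive only inside the water band dies on extraction
  dead <- numeric(512)
  dead[nosomap:::ppm_band_idx(4.3, 5.0)] <- 1
  dead <- zero_water_region(dead)  # [4.2, 5.1] is zeroed first in pipeline
  expect_error(extract_clinical_range(dead), "dead")
})

test_that("process_fid composes the stages with faithful provenance", {
  p <- build_class_profiles()
  f <- simulate_fid(p$no, 30, seed = 21)
  res <- process_fid(f)
  ppm <- attr(res$features, "ppm")
  expect_equal(ppm[which.max(res$features)], 2.01, tolerance = 0.06)
  expect_false(res$provenance$flip_applied)
  # a flipped twin processes to the same features
  flipped <- f; flipped$samples <- -f$samples
  res_f <- process_fid(flipped)
  expect_true(res_f$provenance$flip_applied)
  expect_equal(as.numeric(res_f$features), as.numeric(res$features),
               tolerance = 1e-9)
  # deterministic
  expect_identical(process_fid(f)$features, res$features)
})
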