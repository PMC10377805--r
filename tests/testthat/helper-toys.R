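# Hand-built FIDs and canonical spectra used as oracles across the suite.

toy_acq <- function() acquisition_defaults()

# FID as an explicit sum of damped complex sinusoids; components is a list
# of c(ppm, amplitude, linewidth_ppm)
toy_fid <- function(components, acq = toy_acq(), n = acq$n_points) {
  t <- (seq_len(n) - 1L) / acq$bandwidth_hz
  x <- rep(0i, n)
  for (cm in components) {
    f <- (cm[1] - acq$reference_ppm) * acq$transmitter_mhz
    d <- pi * cm[3] * acq$transmitter_mhz
    x <- x + cm[2] * exp((2i * pi * f - d) * t)
  }
  mrs_fid(x, 1 / acq$bandwidth_hz, acq$transmitter_mhz, acq$reference_ppm)
}

# canonical spectrum with unit-SD noise-region values (deterministic) and a
# chosen set of peaks in the signal band
toy_canonical <- function(peaks = list(), noise_amp = 1) {
  v <- numeric(512)
  ni <- nosomap:::snr_noise_idx()
  # alternating +/- pattern with exact zero mean and unit SD over 89 bins
  pat <- rep(c(-1, 1), length.out = length(ni) - 1L)
  v[ni] <- c(pat, 0) * noise_amp
  for (p in peaks) v[nearest_bin_pub(p[1])] <- p[2]
  v
}

nearest_bin_pub <- function(ppm_value) {
  which.min(abs(canonical_ppm() - ppm_value))
}

write_cfg <- function(dir, ...) {
  p <- file.path(dir, "cfg.txt")
  writeLines(c(...), p)
  p
}

# a bare nosological map built by hand (bypasses classify_grid)
toy_map <- function(classes, posteriors = rep(1, length(classes)),
                    excluded = rep(FALSE, length(classes)),
                    dims = c(length(classes), 1L, 1L),
                    task = class_task("four_class")) {
  classes[excluded] <- NA_character_
  structure(list(
    voxels = data.frame(voxel = seq_along(classes), class = classes,
                        posterior = ifelse(excluded, NA_real_, posteriors),
                        excluded = excluded,
                        reason = ifelse(excluded, "discarded_artifact",
                                        NA_character_)),
    dims = as.integer(dims), task = task, colors = class_colors()),
    class = "nosological_map")
}
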