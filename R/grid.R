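# Canonical 512-point chemical-shift grid shared by every stage of the
# pipeline. With zero-based index i = 0..511 the mapping is
#   ppm(i) = 7.1 - i * (9.8 / 511)
# so index 0 sits at 7.1 ppm (high field left, the usual display convention)
# and index 511 at -2.7 ppm. All R-level vectors are 1-based; helpers below
# return 1-based index ranges.

CANONICAL_N <- 512L
CANONICAL_PPM_MAX <- 7.1
CANONICAL_PPM_MIN <- -2.7
CANONICAL_STEP <- (CANONICAL_PPM_MAX - CANONICAL_PPM_MIN) / (CANONICAL_N - 1L)

#' Canonical ppm axis
#'
#' The fixed 512-point chemical-shift axis used throughout the pipeline,
#' descending from 7.1 to -2.7 ppm.
#'
#' @return Numeric vector of length 512, \code{ppm[i+1] = 7.1 - i * 9.8/511}.
#' @export
canonical_ppm <- function() {
  CANONICAL_PPM_MAX - (seq_len(CANONICAL_N) - 1L) * CANONICAL_STEP
}

# 1-based indices whose ppm lies in [lo, hi] (inclusive both ends).
ppm_band_idx <- function(lo, hi) {
  ppm <- canonical_ppm()
  which(ppm >= lo - 1e-12 & ppm <= hi + 1e-12)
}

# Fixed bands, computed once at load.
water_zero_idx    <- function() ppm_band_idx(4.2, 5.1)    # zeroed region
clinical_idx      <- function() ppm_band_idx(0.0, 4.2)    # classified range
snr_signal_idx    <- function() ppm_band_idx(0.5, 4.1)    # SNR numerator
snr_noise_idx     <- function() ppm_band_idx(-2.7, -1.0)  # SNR denominator

# Nearest canonical bin (1-based) for a ppm value.
nearest_bin <- function(ppm_value) {
  i <- round((CANONICAL_PPM_MAX - ppm_value) / CANONICAL_STEP) + 1
  as.integer(pmin(pmax(i, 1L), CANONICAL_N))
}
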