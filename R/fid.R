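#' Construct a free induction decay (FID) object
#'
#' An FID is the complex time-domain MR signal together with the acquisition
#' metadata needed to map its Fourier transform onto a chemical-shift axis.
#'
#' @param samples Complex vector of time-domain samples.
#' @param dwell_time Sampling interval in seconds (> 0).
#' @param transmitter_mhz Transmitter (Larmor) frequency in MHz; 63.87 is a
#'   1.5 T proton system, 127.74 a 3 T system.
#' @param reference_ppm Chemical shift assigned to zero frequency offset;
#'   water at 4.7 ppm by convention.
#' @param meta Optional named list of extra metadata (carried, not used).
#' @return An object of class \code{mrs_fid}.
#' @export
mrs_fid <- function(samples, dwell_time, transmitter_mhz,
                    reference_ppm = 4.7, meta = list()) {
  if (!is.complex(samples)) samples <- as.complex(samples)
  if (length(samples) < 2L) stop("FID needs at least 2 samples")
  if (!is.numeric(dwell_time) || dwell_time <= 0) stop("dwell_time must be > 0")
  if (!is.numeric(transmitter_mhz) || transmitter_mhz <= 0)
    stop("transmitter_mhz must be > 0")
  structure(
    list(samples = samples, n_points = length(samples),
         dwell_time = dwell_time, transmitter_mhz = transmitter_mhz,
         reference_ppm = reference_ppm, meta = meta),
    class = "mrs_fid")
}

#' @export
print.mrs_fid <- function(x, ...) {
  cat(sprintf("<mrs_fid> %d complex points, dwell %.6g s (bw %.4g Hz), %.4g MHz, ref %.3g ppm\n",
              x$n_points, x$dwell_time, 1 / x$dwell_time, x$transmitter_mhz,
              x$reference_ppm))
  invisible(x)
}

#' Fourier transform an FID to the frequency domain
#'
#' Applies optional exponential apodization, zero-fills, and computes the
#' discrete Fourier transform, returning the complex spectrum on an ascending
#' frequency axis converted to ppm via the transmitter frequency and the
#' reference shift.
#'
#' @param fid An \code{mrs_fid}.
#' @param apodization_hz Exponential line-broadening in Hz (0 disables; the
#'   default). The FID is multiplied by \code{exp(-pi * lb * t)}.
#' @param zero_fill Integer zero-filling factor (>= 1). Zero-filling
#'   interpolates the spectrum without changing its information content; the
#'   default 4 gives a frequency grid finer than the canonical ppm grid so
#'   that resampling is accurate.
#' @return List with components \code{values} (complex spectrum), \code{ppm}
#'   (descending chemical-shift axis, same length) and \code{hz} (frequency
#'   offsets in Hz).
#' @export
fid_to_spectrum <- function(fid, apodization_hz = 0, zero_fill = 4L) {
  stopifnot(inherits(fid, "mrs_fid"))
  if (is.null(fid$dwell_time) || is.null(fid$transmitter_mhz))
    stop("FID is missing acquisition metadata (dwell_time / transmitter_mhz)")
  n <- fid$n_points
  x <- fid$samples
  if (apodization_hz > 0) {
    t <- (seq_len(n) - 1L) * fid$dwell_time
    x <- x * exp(-pi * apodization_hz * t)
  }
  m <- n * max(1L, as.integer(zero_fill))
  xf <- stats::fft(c(x, complex(real = rep(0, m - n))))
  # unshifted fft bin j (0-based) corresponds to frequency j/(m*dt) for
  # j < m/2 and j/(m*dt) - 1/dt for j >= m/2; reorder to ascending frequency
  j <- 0:(m - 1L)
  freq <- j / (m * fid$dwell_time)
  freq[j >= m / 2] <- freq[j >= m / 2] - 1 / fid$dwell_time
  ord <- order(freq)
  freq <- freq[ord]
  vals <- xf[ord]
  ppm <- fid$reference_ppm + freq / fid$transmitter_mhz
  # return in descending-ppm (display) order
  list(values = rev(vals), ppm = rev(ppm), hz = rev(freq))
}
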