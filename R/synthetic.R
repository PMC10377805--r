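# Synthetic single-voxel datasets and multivoxel phantoms. The simulator
# emits FIDs built as sums of exponentially damped complex sinusoids
# (Lorentzian lines), one per metabolite resonance, with class-specific
# amplitude templates, between-subject amplitude variability, broad baseline
# components, and the artifact types seen in real multivoxel grids: flipped
# (inverted) spectra, residual water, low SNR, frequency misalignment and
# ghosting. Templates follow the qualitative patterns reported for brain
# tumor spectra (necrotic aggressive tumors with high lipids at 0.9/1.28 ppm,
# normal tissue with NAA at 2.01 ppm as the tallest peak, meningioma with
# high choline and near-absent NAA/creatine, low-grade glioma with partly
# preserved NAA and an elevated 2.3-2.4 ppm region); exact amplitudes are
# package defaults, configurable per class.

#' Metabolite resonance
#'
#' @param name Resonance name.
#' @param center Chemical shift in ppm, inside [-2.7, 7.1].
#' @param linewidth Lorentzian full width at half maximum, ppm (> 0).
#' @param amplitude Relative height (>= 0).
#' @return A \code{resonance} object (named list).
#' @export
resonance <- function(name, center, linewidth, amplitude) {
  if (center < CANONICAL_PPM_MIN || center > CANONICAL_PPM_MAX)
    stop("resonance center outside [-2.7, 7.1] ppm: ", center)
  if (linewidth <= 0) stop("linewidth must be > 0")
  if (amplitude < 0) stop("amplitude must be >= 0")
  structure(list(name = name, center = center, linewidth = linewidth,
                 amplitude = amplitude), class = "resonance")
}

#' Per-class spectral profile
#'
#' @param class_label One of \code{mm}, \code{gb}, \code{me}, \code{lgg},
#'   \code{no} (or an internal mixed label).
#' @param resonances List of \code{\link{resonance}} objects; must include
#'   NAA, Cho and Cr entries (possibly near-zero amplitude).
#' @param amplitude_cv Relative between-subject variability of each
#'   resonance amplitude (>= 0).
#' @param baseline_level Amplitude of a broad macromolecular baseline
#'   component relative to the largest resonance.
#' @return A \code{class_profile} object.
#' @export
class_profile <- function(class_label, resonances, amplitude_cv = 0.25,
                          baseline_level = 0.1) {
  if (amplitude_cv < 0) stop("amplitude_cv must be >= 0")
  nm <- vapply(resonances, function(r) r$name, character(1))
  for (required in c("NAA", "Cho", "Cr"))
    if (!required %in% nm)
      stop("profile for ", class_label, " lacks required resonance ", required)
  structure(list(class_label = class_label, resonances = resonances,
                 amplitude_cv = amplitude_cv, baseline_level = baseline_level),
            class = "class_profile")
}

# helper to build a profile from a named amplitude vector
profile_from_amplitudes <- function(label, amps, amplitude_cv = 0.25,
                                    baseline_level = 0.1) {
  pos <- c(NAA = 2.01, Cho = 3.21, Cr = 3.03, mI = 3.56, Glx = 2.38,
           Lip13 = 1.28, Lip09 = 0.90, Ala = 1.47)
  lw <- c(NAA = 0.055, Cho = 0.05, Cr = 0.05, mI = 0.06, Glx = 0.09,
          Lip13 = 0.12, Lip09 = 0.12, Ala = 0.07)
  res <- lapply(names(pos), function(m)
    resonance(m, pos[[m]], lw[[m]], if (m %in% names(amps)) amps[[m]] else 0))
  class_profile(label, res, amplitude_cv = amplitude_cv,
                baseline_level = baseline_level)
}

#' Default class profiles
#'
#' Builds the five diagnostic-class profiles (\code{mm} meningioma, \code{gb}
#' glioblastoma, \code{me} metastasis, \code{lgg} low-grade glioma, \code{no}
#' normal white matter). \code{gb} and \code{me} are distinct profiles both
#' mapped to the aggressive superclass \code{agg} downstream.
#'
#' @param config Optional named list; each entry either a
#'   \code{\link{class_profile}} replacing the default, or a list with any of
#'   \code{amplitudes} (named vector over NAA, Cho, Cr, mI, Glx, Lip13,
#'   Lip09, Ala), \code{amplitude_cv}, \code{baseline_level}.
#' @return Named list of five \code{class_profile} objects.
#' @export
build_class_profiles <- function(config = NULL) {
  defaults <- list(
    no  = c(NAA = 1.0, Cr = 0.62, Cho = 0.45, mI = 0.30, Glx = 0.25,
            Lip13 = 0.05, Lip09 = 0.04),
    gb  = c(Lip13 = 1.30, Lip09 = 0.90, Cho = 0.55, Glx = 0.35, Cr = 0.25,
            NAA = 0.20, mI = 0.15),
    me  = c(Lip13 = 1.20, Lip09 = 1.00, Cho = 0.60, Glx = 0.25, Cr = 0.12,
            NAA = 0.12, mI = 0.10),
    mm  = c(Cho = 1.00, Glx = 0.45, Ala = 0.30, Lip13 = 0.15, Lip09 = 0.10,
            Cr = 0.15, NAA = 0.10),
    lgg = c(Cho = 0.75, NAA = 0.65, Cr = 0.50, mI = 0.45, Glx = 0.40,
            Lip13 = 0.06, Lip09 = 0.05))
  profiles <- lapply(names(defaults), function(cl)
    profile_from_amplitudes(cl, defaults[[cl]]))
  names(profiles) <- names(defaults)
  if (!is.null(config)) {
    for (cl in names(config)) {
      if (!cl %in% names(profiles))
        stop("unknown class name in profile config: ", cl)
      entry <- config[[cl]]
      if (inherits(entry, "class_profile")) {
        profiles[[cl]] <- entry
      } else {
        amps <- if (!is.null(entry$amplitudes)) entry$amplitudes else defaults[[cl]]
        profiles[[cl]] <- profile_from_amplitudes(
          cl, amps,
          amplitude_cv = entry$amplitude_cv %||% profiles[[cl]]$amplitude_cv,
          baseline_level = entry$baseline_level %||% profiles[[cl]]$baseline_level)
      }
    }
  }
  profiles
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Artifact specification
#'
#' Per-voxel probabilities and magnitudes of the artifact types injected by
#' the simulator.
#'
#' @param flip_prob Probability of a 180 degree inversion of the FID.
#' @param low_snr_prob Probability the voxel is simulated at very low SNR.
#' @param residual_water_prob Probability of an unsuppressed residual water
#'   component at 4.7 ppm.
#' @param shift_sd SD (ppm) of a Normal(0, shift_sd) frequency misalignment
#'   applied to all resonances.
#' @param ghosting_prob Probability of a spurious ghost peak at a random
#'   position.
#' @return An \code{artifact_spec} object.
#' @export
artifact_spec <- function(flip_prob = 0, low_snr_prob = 0,
                          residual_water_prob = 0, shift_sd = 0,
                          ghosting_prob = 0) {
  p <- c(flip_prob, low_snr_prob, residual_water_prob, ghosting_prob)
  if (any(p < 0 | p > 1)) stop("artifact probabilities must be in [0, 1]")
  if (shift_sd < 0) stop("shift_sd must be >= 0")
  structure(list(flip_prob = flip_prob, low_snr_prob = low_snr_prob,
                 residual_water_prob = residual_water_prob,
                 shift_sd = shift_sd, ghosting_prob = ghosting_prob),
            class = "artifact_spec")
}

#' Default acquisition parameters
#'
#' 1024 complex points at 2404 Hz bandwidth (typical short-TE values), 63.87
#' MHz transmitter (1.5 T proton), water reference at 4.7 ppm. The implied
#' ppm coverage (about [-14, 23]) contains the canonical [-2.7, 7.1] range.
#'
#' @param n_points,bandwidth_hz,transmitter_mhz,reference_ppm Overrides.
#' @return Named list of acquisition parameters.
#' @export
acquisition_defaults <- function(n_points = 1024L, bandwidth_hz = 2404,
                                 transmitter_mhz = 63.87,
                                 reference_ppm = 4.7) {
  list(n_points = as.integer(n_points), bandwidth_hz = bandwidth_hz,
       transmitter_mhz = transmitter_mhz, reference_ppm = reference_ppm)
}

# Time-domain signal of one Lorentzian line: amplitude * exp((2i pi f - d) t)
# with d = pi * FWHM_Hz. Accumulated into a complex vector.
lorentzian_fid <- function(amps, centers_ppm, lw_ppm, acq) {
  t <- (seq_len(acq$n_points) - 1L) / acq$bandwidth_hz
  out <- rep(0i, acq$n_points)
  for (k in seq_along(amps)) {
    if (amps[k] <= 0) next
    f <- (centers_ppm[k] - acq$reference_ppm) * acq$transmitter_mhz
    d <- pi * lw_ppm[k] * acq$transmitter_mhz
    out <- out + amps[k] * exp((2i * pi * f - d) * t)
  }
  out
}

#' Simulate one FID from a class profile
#'
#' The FID is a sum of exponentially damped complex sinusoids at the
#' profile's resonance positions (amplitudes jittered by the profile's
#' between-subject CV), a broad baseline component, the artifacts drawn from
#' \code{artifacts}, and complex white noise scaled so that the
#' frequency-domain SNR (peak height over noise SD, as measured by
#' \code{\link{estimate_snr}}) is close to \code{snr_target}.
#'
#' @param profile A \code{\link{class_profile}}.
#' @param snr_target Target SNR (> 0).
#' @param artifacts An \code{\link{artifact_spec}}.
#' @param seed Integer seed; identical inputs give bitwise-identical output.
#' @param acq Acquisition parameters, see \code{\link{acquisition_defaults}}.
#' @return An \code{mrs_fid}; attribute \code{"artifacts"} is a character
#'   vector of the artifact types that fired, attribute \code{"true_class"}
#'   the profile label.
#' @export
simulate_fid <- function(profile, snr_target, artifacts = artifact_spec(),
                         seed = 1L, acq = acquisition_defaults()) {
  stopifnot(inherits(profile, "class_profile"))
  if (snr_target <= 0) stop("snr_target must be > 0")
  set.seed(seed)
  fired <- character(0)
  amps <- vapply(profile$resonances, function(r) r$amplitude, numeric(1))
  centers <- vapply(profile$resonances, function(r) r$center, numeric(1))
  lw <- vapply(profile$resonances, function(r) r$linewidth, numeric(1))
  cv <- profile$amplitude_cv
  if (cv > 0) amps <- pmax(amps * (1 + cv * stats::rnorm(length(amps))), 0)
  # broad macromolecular baseline (smooth distortion across the range)
  if (profile$baseline_level > 0 && any(amps > 0)) {
    amps <- c(amps, profile$baseline_level * max(amps))
    centers <- c(centers, 1.6)
    lw <- c(lw, 2.5)
  }
  shift <- 0
  if (artifacts$shift_sd > 0) {
    shift <- stats::rnorm(1, 0, artifacts$shift_sd)
    if (abs(shift) > 1e-12) fired <- c(fired, "shift")
  }
  centers <- centers + shift
  if (stats::runif(1) < artifacts$residual_water_prob) {
    fired <- c(fired, "residual_water")
    amps <- c(amps, 4 * max(amps, 1))
    centers <- c(centers, acq$reference_ppm + stats::runif(1, -0.05, 0.05))
    lw <- c(lw, 0.15)
  }
  if (stats::runif(1) < artifacts$ghosting_prob) {
    fired <- c(fired, "ghost")
    amps <- c(amps, 0.8 * max(amps, 0.5))
    centers <- c(centers, stats::runif(1, 0.3, 4.0))
    lw <- c(lw, 0.08)
  }
  centers <- pmin(pmax(centers, CANONICAL_PPM_MIN), CANONICAL_PPM_MAX)
  clean <- lorentzian_fid(amps, centers, lw, acq)
  snr_used <- snr_target
  if (stats::runif(1) < artifacts$low_snr_prob) {
    fired <- c(fired, "low_snr")
    snr_used <- stats::runif(1, 2, 6)
  }
  fid <- mrs_fid(clean, dwell_time = 1 / acq$bandwidth_hz,
                 transmitter_mhz = acq$transmitter_mhz,
                 reference_ppm = acq$reference_ppm)
  # scale complex white noise so the canonical-grid peak/noise ratio matches
  # snr_target: DFT of n iid complex normals has real-part SD sigma*sqrt(n)
  peak <- if (any(amps > 0)) {
    vals <- resample_to_canonical(fid_to_spectrum(fid))
    sig <- vals[snr_signal_idx()]
    max(sig) - stats::median(sig)
  } else 0
  n <- acq$n_points
  sigma <- if (peak > 0) peak / (snr_used * sqrt(n)) else 1
  noise <- complex(real = stats::rnorm(n, 0, sigma),
                   imaginary = stats::rnorm(n, 0, sigma))
  samples <- clean + noise
  if (stats::runif(1) < artifacts$flip_prob) {
    fired <- c(fired, "flip")
    samples <- -samples
  }
  out <- mrs_fid(samples, dwell_time = 1 / acq$bandwidth_hz,
                 transmitter_mhz = acq$transmitter_mhz,
                 reference_ppm = acq$reference_ppm)
  attr(out, "artifacts") <- fired
  attr(out, "true_class") <- profile$class_label
  out
}

#' Class counts of the reference single-voxel training database
#'
#' The published training set holds 22 normal volunteers, 62 meningiomas,
#' 123 aggressive tumors (85 glioblastomas + 38 metastases) and 35 low-grade
#' glial tumors.
#'
#' @return Named integer vector \code{c(no = 22, mm = 62, agg = 123, lgg = 35)}.
#' @export
sv_class_counts <- function() c(no = 22L, mm = 62L, agg = 123L, lgg = 35L)

#' Simulate a labeled single-voxel dataset
#'
#' @param n_per_class Named vector of requested counts; names among
#'   \code{no}, \code{mm}, \code{gb}, \code{me}, \code{lgg}, \code{agg}. An
#'   \code{agg} request is split between the \code{gb} and \code{me} profiles
#'   in the 85:38 proportion of the reference database. Use
#'   \code{\link{sv_class_counts}} for the reference class-imbalance preset.
#' @param snr_range Two-element range; each voxel's target SNR is drawn
#'   uniformly from it.
#' @param artifacts \code{\link{artifact_spec}} applied per FID (default:
#'   none — the reference single-voxel database is curated, artifact-free
#'   data).
#' @param seed Integer seed.
#' @param profiles Profiles from \code{\link{build_class_profiles}}.
#' @param acq Acquisition parameters.
#' @return List with \code{fids} (list of \code{mrs_fid}), \code{labels}
#'   (requested class names, e.g. \code{agg}), \code{fine_labels} (profile
#'   actually used, e.g. \code{gb}).
#' @export
simulate_sv_dataset <- function(n_per_class, snr_range = c(12, 35),
                                artifacts = artifact_spec(), seed = 1L,
                                profiles = build_class_profiles(),
                                acq = acquisition_defaults()) {
  if (length(n_per_class) == 0L) stop("empty class list")
  if (is.null(names(n_per_class)) || any(names(n_per_class) == ""))
    stop("n_per_class must be a named vector")
  bad <- setdiff(names(n_per_class), c(names(profiles), "agg"))
  if (length(bad)) stop("unknown class name(s): ", paste(bad, collapse = ", "))
  if (any(n_per_class < 1)) stop("n_per_class entries must be >= 1")
  set.seed(seed)
  labels <- character(0); fine <- character(0)
  for (cl in names(n_per_class)) {
    n <- n_per_class[[cl]]
    if (cl == "agg") {
      n_gb <- round(n * 85 / 123)
      f <- c(rep("gb", n_gb), rep("me", n - n_gb))
    } else f <- rep(cl, n)
    labels <- c(labels, rep(cl, n))
    fine <- c(fine, f)
  }
  seeds <- sample.int(.Machine$integer.max, length(fine))
  snrs <- stats::runif(length(fine), snr_range[1], snr_range[2])
  fids <- lapply(seq_along(fine), function(i)
    simulate_fid(profiles[[fine[i]]], snr_target = snrs[i],
                 artifacts = artifacts, seed = seeds[i], acq = acq))
  list(fids = fids, labels = labels, fine_labels = fine)
}

# convex combination of two profiles' resonance lists (partial volume /
# infiltration mixing)
mix_profiles <- function(p1, p2, w1, label = "mixed") {
  res <- c(
    lapply(p1$resonances, function(r)
      resonance(r$name, r$center, r$linewidth, w1 * r$amplitude)),
    lapply(p2$resonances, function(r)
      resonance(paste0(r$name, "'"), r$center, r$linewidth,
                (1 - w1) * r$amplitude)))
  # required names must still be present: keep p1's names unprimed
  structure(list(class_label = label, resonances = res,
                 amplitude_cv = (p1$amplitude_cv + p2$amplitude_cv) / 2,
                 baseline_level = w1 * p1$baseline_level +
                   (1 - w1) * p2$baseline_level),
            class = "class_profile")
}

#' Default phantom geometry
#'
#' An elliptical solid tumor core, a surrounding abnormal ring, an optional
#' ventricle patch, normal tissue elsewhere.
#'
#' @param dims Grid dimensions (nx, ny, nz).
#' @param ventricle Include a ventricle patch?
#' @return Geometry list used by \code{\link{simulate_mv_phantom}}.
#' @export
phantom_geometry <- function(dims, ventricle = TRUE) {
  nx <- dims[1]; ny <- dims[2]
  list(solid_center = c(round(0.38 * nx), round(0.5 * ny)),
       solid_radius = c(max(2, round(nx / 6)), max(2, round(ny / 5))),
       abnormal_width = 2,
       ventricle = ventricle,
       ventricle_box = c(x0 = max(1, round(0.78 * nx)), y0 = max(1, round(0.2 * ny)),
                         w = 2, h = 2))
}

#' Simulate a multivoxel phantom
#'
#' Generates a grid of voxel FIDs with a ground-truth tissue mask: a
#' contiguous solid region of the case's tumor class, a surrounding abnormal
#' ring (infiltrative tumor/normal mixture for glial cases; oedema-like
#' normal-dominated mixture for meningioma/metastasis), normal tissue
#' elsewhere and an optional ventricle patch (low-signal CSF-like voxels).
#' Voxels on region boundaries are simulated from a 50/50 convex mixture of
#' the adjacent profiles, emulating voxel bleeding.
#'
#' @param dims Integer (nx, ny, nz).
#' @param case_class Diagnostic class of the simulated patient: \code{gb},
#'   \code{me}, \code{mm}, \code{lgg} or \code{no} (no tumor).
#' @param geometry See \code{\link{phantom_geometry}} (default geometry if
#'   NULL).
#' @param artifacts \code{\link{artifact_spec}} applied independently per
#'   voxel.
#' @param snr_range Per-voxel target SNR range.
#' @param seed Integer seed.
#' @param profiles Class profiles.
#' @param acq Acquisition parameters; the default 3 T transmitter (127.74
#'   MHz) mimics a multivoxel test acquisition at a field strength different
#'   from the training data.
#' @return An \code{mrs_phantom}: list with \code{dims}, \code{case_class},
#'   \code{fids} (voxel-major list, x fastest then y then z), \code{truth}
#'   (character vector in \code{normal}, \code{solid}, \code{abnormal},
#'   \code{ventricle}), \code{artifact_log} (list of character vectors),
#'   \code{seed}.
#' @export
simulate_mv_phantom <- function(dims, case_class, geometry = NULL,
                                artifacts = artifact_spec(),
                                snr_range = c(12, 35), seed = 1L,
                                profiles = build_class_profiles(),
                                acq = acquisition_defaults(transmitter_mhz = 127.74)) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 1L)) stop("dims must be 3 positive integers")
  stopifnot(case_class %in% c(names(profiles), "no"))
  geometry <- geometry %||% phantom_geometry(dims, ventricle = case_class != "no")
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  if (case_class != "no") {
    if (geometry$solid_center[1] + geometry$solid_radius[1] > nx ||
        geometry$solid_center[2] + geometry$solid_radius[2] > ny)
      stop("geometry exceeds dims")
  }
  truth <- character(nx * ny * nz)
  vox <- function(x, y, z) x + (y - 1L) * nx + (z - 1L) * nx * ny
  for (z in seq_len(nz)) for (y in seq_len(ny)) for (x in seq_len(nx)) {
    lab <- "normal"
    if (case_class != "no") {
      dx <- (x - geometry$solid_center[1]) / geometry$solid_radius[1]
      dy <- (y - geometry$solid_center[2]) / geometry$solid_radius[2]
      r2 <- dx^2 + dy^2
      rx_ab <- geometry$solid_radius[1] + geometry$abnormal_width
      ry_ab <- geometry$solid_radius[2] + geometry$abnormal_width
      r2_ab <- ((x - geometry$solid_center[1]) / rx_ab)^2 +
        ((y - geometry$solid_center[2]) / ry_ab)^2
      if (r2 <= 1) lab <- "solid" else if (r2_ab <= 1) lab <- "abnormal"
      if (isTRUE(geometry$ventricle)) {
        vb <- geometry$ventricle_box
        if (x >= vb["x0"] && x < vb["x0"] + vb["w"] &&
            y >= vb["y0"] && y < vb["y0"] + vb["h"] && lab == "normal")
          lab <- "ventricle"
      }
    }
    truth[vox(x, y, z)] <- lab
  }
  if (case_class != "no" && !any(truth == "solid"))
    stop("geometry produced an empty solid region")
  tumor_profile <- profiles[[if (case_class == "no") "no" else case_class]]
  oedema <- profile_from_amplitudes("oedema", c(
    NAA = 0.55, Cr = 0.45, Cho = 0.45, mI = 0.25, Glx = 0.25,
    Lip13 = 0.35, Lip09 = 0.25))
  abnormal_profile <- if (case_class %in% c("gb", "lgg")) {
    mix_profiles(tumor_profile, profiles$no, 0.5, "infiltrative")
  } else if (case_class %in% c("mm", "me")) {
    mix_profiles(profiles$no, oedema, 0.6, "peritumoral")
  } else profiles$no
  ventricle_profile <- profile_from_amplitudes("ventricle", c(
    NAA = 0.12, Cr = 0.08, Cho = 0.07), amplitude_cv = 0.3,
    baseline_level = 0.05)
  label_profile <- function(lab) switch(lab,
    normal = profiles$no, solid = tumor_profile,
    abnormal = abnormal_profile, ventricle = ventricle_profile)
  set.seed(seed)
  nvox <- nx * ny * nz
  seeds <- sample.int(.Machine$integer.max, nvox)
  snrs <- stats::runif(nvox, snr_range[1], snr_range[2])
  fids <- vector("list", nvox)
  artifact_log <- vector("list", nvox)
  for (z in seq_len(nz)) for (y in seq_len(ny)) for (x in seq_len(nx)) {
    i <- vox(x, y, z)
    lab <- truth[i]
    prof <- label_profile(lab)
    # partial-volume bleeding: a boundary voxel receives a 50% contribution
    # from the most severe differing in-slice 4-neighbor, but only when that
    # neighbor is MORE severe (bleeding spreads the strong tumor signal
    # outward; a solid core's own signal dominates its voxel)
    severity <- c(ventricle = 0, normal = 1, abnormal = 2, solid = 3)
    nbr <- c(if (x > 1) truth[vox(x - 1, y, z)],
             if (x < nx) truth[vox(x + 1, y, z)],
             if (y > 1) truth[vox(x, y - 1, z)],
             if (y < ny) truth[vox(x, y + 1, z)])
    worse <- nbr[severity[nbr] > severity[lab]]
    if (length(worse) > 0) {
      src <- worse[which.max(severity[worse])]
      prof <- mix_profiles(prof, label_profile(src), 0.5,
                           paste0(lab, "+", src))
    }
    f <- simulate_fid(prof, snr_target = snrs[i], artifacts = artifacts,
                      seed = seeds[i], acq = acq)
    fids[[i]] <- f
    artifact_log[[i]] <- attr(f, "artifacts")
  }
  structure(list(dims = dims, case_class = case_class, fids = fids,
                 truth = truth, artifact_log = artifact_log, seed = seed,
                 geometry = geometry),
            class = "mrs_phantom")
}

#' @export
print.mrs_phantom <- function(x, ...) {
  cat(sprintf("<mrs_phantom> %dx%dx%d, case %s\n", x$dims[1], x$dims[2],
              x$dims[3], x$case_class))
  print(table(x$truth))
  invisible(x)
}
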