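# Nosological maps: per-voxel winning class and posterior rendered as a
# color-coded image (blue = normal, red = aggressive, green = low-grade
# glioma, yellow = meningioma; excluded voxels black at 0.5 alpha), scored
# against the ground-truth tissue mask with the Solid Tumor Index (STI),
# per-class Dice overlap, and BER / per-class AUC restricted to the solid
# and normal regions.

#' Class color assignment
#'
#' @return Named vector of hex colors: no = blue, agg = red, lgg = green,
#'   mm = yellow.
#' @export
class_colors <- function() {
  c(no = "#0000FF", agg = "#FF0000", lgg = "#00B200", mm = "#FFD700")
}

#' Classify a multivoxel grid into a nosological map
#'
#' Kept voxels get the winning class and its posterior; voxels excluded by
#' quality control carry their exclusion reason instead.
#'
#' @param model A fitted classifier (answers \code{\link{predict_scores}}).
#' @param features n_voxel x p matrix of processed voxel spectra on the
#'   model's feature columns.
#' @param qc Optional \code{\link{qc_screen}} result aligned to the voxels;
#'   NULL keeps everything.
#' @param task The \code{\link{class_task}}.
#' @param dims Grid dimensions (nx, ny, nz).
#' @return A \code{nosological_map}: data.frame \code{voxels} (voxel, class,
#'   posterior, excluded, reason) plus \code{dims}, \code{task},
#'   \code{colors}.
#' @export
classify_grid <- function(model, features, qc = NULL, task = class_task(),
                          dims = c(nrow(features), 1L, 1L)) {
  n <- nrow(features)
  if (!is.null(qc) && nrow(qc) != n)
    stop("qc result does not match the number of voxels")
  scores <- predict_scores(model, features)
  cls <- score_labels(scores)
  post <- scores[cbind(seq_len(n), match(cls, colnames(scores)))]
  excluded <- rep(FALSE, n); reason <- rep(NA_character_, n)
  if (!is.null(qc)) {
    excluded <- qc$status != "kept"
    reason[excluded] <- qc$status[excluded]
  }
  cls[excluded] <- NA_character_
  post[excluded] <- NA_real_
  structure(list(
    voxels = data.frame(voxel = seq_len(n), class = cls, posterior = post,
                        excluded = excluded, reason = reason),
    dims = as.integer(dims), task = task, colors = class_colors()),
    class = "nosological_map")
}

#' Solid Tumor Index
#'
#' STI = (number of solid-region voxels classified as the case's class) /
#' (number of solid-region voxels - solid-region voxels excluded by quality
#' control). An STI above 0.50 is counted as a successful case.
#'
#' @param map A \code{nosological_map}.
#' @param truth_mask Character truth labels per voxel (\code{normal},
#'   \code{solid}, \code{abnormal}, \code{ventricle}).
#' @param case_class The patient's diagnostic class (gb/me are mapped to
#'   agg).
#' @return List with \code{sti} and \code{success} (STI > 0.50).
#' @export
sti <- function(map, truth_mask, case_class) {
  v <- map$voxels
  target <- map_to_task(case_class, map$task)
  if (is.na(target)) stop("case class not in task: ", case_class)
  solid <- truth_mask == "solid"
  denom <- sum(solid) - sum(solid & v$excluded)
  if (denom <= 0) stop("no solid-region voxels left after exclusions")
  num <- sum(solid & !v$excluded & v$class == target, na.rm = TRUE)
  list(sti = num / denom, success = (num / denom) > 0.50)
}

#' Dice overlap between a truth region and a predicted class
#'
#' 2|A intersect B| / (|A| + |B|), computed over non-excluded voxels.
#' Undefined (both sets empty) is reported as NA, not 0.
#'
#' @param map A \code{nosological_map}.
#' @param truth_mask Truth labels per voxel.
#' @param region Truth region name (\code{solid}, \code{normal},
#'   \code{abnormal}).
#' @param predicted_class Task class paired with the region.
#' @return Dice fraction in [0, 1], or NA if undefined.
#' @export
dice <- function(map, truth_mask, region, predicted_class) {
  v <- map$voxels
  ok <- !v$excluded
  A <- ok & truth_mask == region
  B <- ok & !is.na(v$class) & v$class == predicted_class
  if (sum(A) + sum(B) == 0L) return(NA_real_)
  2 * sum(A & B) / (sum(A) + sum(B))
}

# region-to-class pairing used for the Dice table: normal <-> no,
# solid <-> case class; abnormal <-> lgg for glial cases in the 4-class task
# (infiltration reads as low-grade), else the case class itself
dice_pairing <- function(case_class, task) {
  target <- map_to_task(case_class, task)
  abnormal_class <- if (task$name == "four_class" &&
                        case_class %in% c("gb", "lgg")) "lgg" else target
  c(normal = "no", solid = target, abnormal = abnormal_class)
}

#' Score a classified grid against its ground truth
#'
#' Computes, per z-slice and overall: STI, per-region Dice, and BER with
#' per-class one-vs-rest AUC restricted to the solid (labelled with the case
#' class) and normal (labelled no) voxels — abnormal and excluded voxels are
#' omitted from BER/AUC, as in the reference evaluation protocol.
#'
#' @param map A \code{nosological_map}.
#' @param truth_mask Truth labels per voxel.
#' @param case_class The case's diagnostic class.
#' @param scores Optional n x K score matrix (for AUC); without it AUC uses
#'   the winning posteriors only for the winning class and is skipped.
#' @return An \code{eval_report}: data.frame with columns case-level
#'   \code{slice} ("all" or z index), \code{metric}, \code{class},
#'   \code{value}.
#' @export
grid_metrics <- function(map, truth_mask, case_class, scores = NULL) {
  v <- map$voxels
  task <- map$task
  target <- map_to_task(case_class, task)
  dims <- map$dims
  nxy <- dims[1] * dims[2]
  slice_of <- rep(seq_len(dims[3]), each = nxy)
  pairing <- dice_pairing(case_class, task)
  rows <- list()
  add <- function(slice, metric, class, value)
    rows[[length(rows) + 1L]] <<- data.frame(
      slice = slice, metric = metric, class = class, value = value,
      stringsAsFactors = FALSE)
  scopes <- c(list(all = rep(TRUE, nrow(v))),
              if (dims[3] > 1)
                stats::setNames(lapply(seq_len(dims[3]),
                                       function(z) slice_of == z),
                                as.character(seq_len(dims[3]))))
  for (scope_name in names(scopes)) {
    in_scope <- scopes[[scope_name]]
    if (case_class != "no" && any(in_scope & truth_mask == "solid")) {
      s <- tryCatch(sti(subset_map(map, in_scope), truth_mask[in_scope],
                        case_class),
                    error = function(e) list(sti = NA_real_, success = NA))
      add(scope_name, "sti", target, s$sti)
    }
    for (region in names(pairing)) {
      if (case_class == "no" && region != "normal") next
      d <- dice(subset_map(map, in_scope), truth_mask[in_scope], region,
                pairing[[region]])
      add(scope_name, "dice", pairing[[region]], d)
    }
    # BER / AUC on solid + normal voxels only
    elig <- in_scope & !v$excluded &
      truth_mask %in% c("solid", "normal") & !is.na(v$class)
    y_true <- ifelse(truth_mask[elig] == "solid", target, "no")
    if (length(unique(y_true)) >= 2) {
      add(scope_name, "ber", NA_character_,
          ber(y_true, v$class[elig], unique(y_true)))
      if (!is.null(scores)) {
        for (cl in intersect(colnames(scores), unique(y_true)))
          add(scope_name, "auc", cl,
              auc_ovr(y_true, scores[elig, cl], cl))
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("eval_report", "data.frame")
  out
}

subset_map <- function(map, keep) {
  map$voxels <- map$voxels[keep, , drop = FALSE]
  map$voxels$voxel <- seq_len(nrow(map$voxels))
  map
}

#' Render a nosological map as an RGBA raster
#'
#' One cell per voxel (a single z-slice), color = winning class, intensity =
#' winning posterior, excluded voxels black with alpha 0.5. Deterministic:
#' the same map always produces the identical array.
#'
#' @param map A \code{nosological_map}.
#' @param slice z-slice to render (default 1).
#' @return An nx x ny x 4 numeric array (RGBA in [0, 1]), suitable for
#'   \code{\link{write_map_png}}.
#' @export
render_map <- function(map, slice = 1L) {
  dims <- map$dims
  nxy <- dims[1] * dims[2]
  off <- (slice - 1L) * nxy
  v <- map$voxels[off + seq_len(nxy), ]
  img <- array(0, dim = c(dims[1], dims[2], 4))
  cols <- map$colors
  for (i in seq_len(nxy)) {
    x <- ((i - 1L) %% dims[1]) + 1L
    y <- ((i - 1L) %/% dims[1]) + 1L
    if (v$excluded[i] || is.na(v$class[i])) {
      img[x, y, ] <- c(0, 0, 0, 0.5)
    } else {
      rgb <- grDevices::col2rgb(cols[[v$class[i]]]) / 255
      img[x, y, ] <- c(rgb * v$posterior[i], 1)
    }
  }
  img
}

#' Write a rendered map to a PNG file
#'
#' Uses the base graphics PNG device when available; drawing is a plain
#' raster of the RGBA array.
#'
#' @param img Array from \code{\link{render_map}}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_map_png <- function(img, path) {
  if (!capabilities("png")) {
    warning("no PNG device available; skipping ", path)
    return(invisible(path))
  }
  nx <- dim(img)[1]; ny <- dim(img)[2]
  # raster wants rows = y (top first), columns = x
  ras <- aperm(img, c(2, 1, 3))[ny:1, , , drop = FALSE]
  grDevices::png(path, width = nx * 20, height = ny * 20)
  op <- graphics::par(mar = c(0, 0, 0, 0))
  graphics::plot.new()
  graphics::rasterImage(grDevices::as.raster(ras), 0, 0, 1, 1,
                        interpolate = FALSE)
  graphics::par(op)
  grDevices::dev.off()
  invisible(path)
}
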