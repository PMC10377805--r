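# File formats. The original SpectraClassifier / jMRUI2XML schema is not
# public, so the package defines a minimal documented XML dialect for
# spectra (canonical 512-point records or raw FID records with acquisition
# metadata) plus an XML mask sidecar, and reads/writes plain delimited
# tables for interoperability.
#
# Spectra document:
#   <spectra version="1" representation="canonical|fid">
#     <record id="..." label="...">          (label optional)
#       canonical: <values>v1 v2 ... v512</values>
#       fid:       <samples dwell_time=".." transmitter_mhz=".."
#                   reference_ppm="..">re,im re,im ...</samples>
#     </record> ...
#   </spectra>
# Mask document:
#   <mask nx=".." ny=".." nz=".." case="..">
#     <labels>normal solid abnormal ventricle ...</labels>
#   </mask>

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a spectra document
#'
#' @param doc List with \code{representation} ("canonical" or "fid") and
#'   \code{records}: for canonical, each record is
#'   \code{list(id, label, values)} with 512 values; for fid,
#'   \code{list(id, label, fid)} with an \code{mrs_fid}. Convenience: a
#'   matrix with optional \code{labels} can be wrapped with
#'   \code{\link{spectra_document}}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_spectra <- function(doc, path) {
  ids <- vapply(doc$records, function(r) as.character(r$id), character(1))
  if (anyDuplicated(ids)) stop("duplicate record identifiers")
  root <- xml2::xml_new_root("spectra", version = "1",
                             representation = doc$representation)
  for (r in doc$records) {
    node <- xml2::xml_add_child(root, "record", id = as.character(r$id))
    if (!is.null(r$label) && !is.na(r$label))
      xml2::xml_set_attr(node, "label", r$label)
    if (doc$representation == "canonical") {
      if (length(r$values) != CANONICAL_N)
        stop("record ", r$id, " has ", length(r$values),
             " values; expected ", CANONICAL_N)
      xml2::xml_add_child(node, "values",
                          paste(fmt_num(r$values), collapse = " "))
    } else {
      f <- r$fid
      s <- xml2::xml_add_child(node, "samples",
                               paste(paste0(fmt_num(Re(f$samples)), ",",
                                            fmt_num(Im(f$samples))),
                                     collapse = " "))
      xml2::xml_set_attr(s, "dwell_time", fmt_num(f$dwell_time))
      xml2::xml_set_attr(s, "transmitter_mhz", fmt_num(f$transmitter_mhz))
      xml2::xml_set_attr(s, "reference_ppm", fmt_num(f$reference_ppm))
    }
  }
  xml2::write_xml(root, path)
  invisible(path)
}

#' Read a spectra document
#'
#' @param path XML file written by \code{\link{write_spectra}}.
#' @return A spectra document list (see \code{\link{write_spectra}}).
#' @export
read_spectra <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  root <- xml2::read_xml(path)
  if (xml2::xml_name(root) != "spectra") stop("not a spectra document")
  rep_kind <- xml2::xml_attr(root, "representation")
  if (!rep_kind %in% c("canonical", "fid"))
    stop("unknown representation: ", rep_kind)
  recs <- xml2::xml_find_all(root, "record")
  ids <- xml2::xml_attr(recs, "id")
  if (anyDuplicated(ids)) stop("duplicate record identifiers")
  records <- lapply(recs, function(node) {
    id <- xml2::xml_attr(node, "id")
    label <- xml2::xml_attr(node, "label")
    if (rep_kind == "canonical") {
      txt <- xml2::xml_text(xml2::xml_find_first(node, "values"))
      vals <- as.numeric(strsplit(trimws(txt), "\\s+")[[1]])
      if (length(vals) != CANONICAL_N)
        stop("record ", id, " has ", length(vals), " values; expected ",
             CANONICAL_N)
      list(id = id, label = label, values = vals)
    } else {
      s <- xml2::xml_find_first(node, "samples")
      pairs <- strsplit(trimws(xml2::xml_text(s)), "\\s+")[[1]]
      parts <- do.call(rbind, strsplit(pairs, ","))
      fid <- mrs_fid(complex(real = as.numeric(parts[, 1]),
                             imaginary = as.numeric(parts[, 2])),
                     dwell_time = as.numeric(xml2::xml_attr(s, "dwell_time")),
                     transmitter_mhz = as.numeric(xml2::xml_attr(s, "transmitter_mhz")),
                     reference_ppm = as.numeric(xml2::xml_attr(s, "reference_ppm")))
      list(id = id, label = label, fid = fid)
    }
  })
  list(representation = rep_kind, records = records)
}

#' Build a spectra document
#'
#' @param x Either an n x 512 matrix of canonical spectra or a list of
#'   \code{mrs_fid} objects.
#' @param labels Optional class labels, one per record.
#' @param ids Optional identifiers (default \code{"r1" ...}).
#' @return A spectra document for \code{\link{write_spectra}}.
#' @export
spectra_document <- function(x, labels = NULL, ids = NULL) {
  n <- if (is.matrix(x)) nrow(x) else length(x)
  ids <- ids %||% paste0("r", seq_len(n))
  records <- lapply(seq_len(n), function(i) {
    lab <- if (is.null(labels)) NULL else labels[i]
    if (is.matrix(x)) list(id = ids[i], label = lab, values = x[i, ])
    else list(id = ids[i], label = lab, fid = x[[i]])
  })
  list(representation = if (is.matrix(x)) "canonical" else "fid",
       records = records)
}

MASK_LABELS <- c("normal", "solid", "abnormal", "ventricle")

#' Write a mask document
#'
#' @param mask List with \code{dims} (nx, ny, nz), \code{labels} (character
#'   vector, voxel-major x fastest) and optional \code{case_class}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_mask <- function(mask, path) {
  if (length(mask$labels) != prod(mask$dims))
    stop("label count does not match dims")
  bad <- setdiff(unique(mask$labels), MASK_LABELS)
  if (length(bad)) stop("unknown label token(s): ", paste(bad, collapse = ", "))
  root <- xml2::xml_new_root("mask", nx = as.character(mask$dims[1]),
                             ny = as.character(mask$dims[2]),
                             nz = as.character(mask$dims[3]))
  if (!is.null(mask$case_class))
    xml2::xml_set_attr(root, "case", mask$case_class)
  xml2::xml_add_child(root, "labels", paste(mask$labels, collapse = " "))
  xml2::write_xml(root, path)
  invisible(path)
}

#' Read a mask document
#'
#' @param path XML file from \code{\link{write_mask}}.
#' @return List with \code{dims}, \code{labels}, \code{case_class}.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  root <- xml2::read_xml(path)
  if (xml2::xml_name(root) != "mask") stop("not a mask document")
  dims <- as.integer(c(xml2::xml_attr(root, "nx"), xml2::xml_attr(root, "ny"),
                       xml2::xml_attr(root, "nz")))
  labels <- strsplit(trimws(xml2::xml_text(
    xml2::xml_find_first(root, "labels"))), "\\s+")[[1]]
  bad <- setdiff(unique(labels), MASK_LABELS)
  if (length(bad)) stop("unknown label token(s): ", paste(bad, collapse = ", "))
  if (length(labels) != prod(dims))
    stop("label count (", length(labels), ") does not match dims (",
         prod(dims), ")")
  list(dims = dims, labels = labels,
       case_class = xml2::xml_attr(root, "case"))
}

#' Write a delimited feature table
#'
#' Tab-separated matrix with an id column and optional label column;
#' formatting is fixed so identical inputs give byte-identical files.
#'
#' @param X Numeric matrix.
#' @param path Output file.
#' @param labels Optional label column.
#' @return \code{path}, invisibly.
#' @export
write_table_tsv <- function(X, path, labels = NULL) {
  X <- as.matrix(X)
  df <- data.frame(id = paste0("r", seq_len(nrow(X))))
  if (!is.null(labels)) df$label <- labels
  num <- apply(X, 2, fmt_num)
  if (is.null(dim(num))) num <- matrix(num, nrow = nrow(X))
  colnames(num) <- colnames(X) %||% paste0("v", seq_len(ncol(X)))
  utils::write.table(cbind(df, num), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Save an LDA model as a JSON parameter file
#'
#' @param model An \code{lda_model}.
#' @param feature_indices Grid indices of the features the model was trained
#'   on.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_lda_model <- function(model, feature_indices, path) {
  jsonlite::write_json(list(
    type = "lda", classes = model$classes,
    feature_indices = feature_indices,
    means = apply(model$means, 1, identity, simplify = FALSE),
    cov = apply(model$cov, 1, identity, simplify = FALSE),
    priors = as.list(model$priors)), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an LDA model parameter file
#'
#' @param path File from \code{\link{write_lda_model}}.
#' @return List with \code{model} (an \code{lda_model}) and
#'   \code{feature_indices}.
#' @export
read_lda_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$type, "lda")) stop("not an LDA model file")
  as_mat <- function(x) if (is.matrix(x)) x else do.call(rbind, x)
  means <- as_mat(j$means)
  rownames(means) <- j$classes
  S <- as_mat(j$cov)
  model <- structure(list(classes = j$classes, means = means, cov = S,
                          cov_inv = solve(S),
                          priors = unlist(j$priors), features = NULL),
                     class = c("lda_model", "nosomap_classifier"))
  list(model = model, feature_indices = j$feature_indices)
}
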