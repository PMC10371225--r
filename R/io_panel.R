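# Panel assembly and delimited-matrix I/O.

#' Average an intensity volume within atlas parcels
#'
#' Computes the arithmetic mean of in-parcel voxel intensities for every
#' nonzero label in `labels`. Label 0 is background and ignored. NaN voxels
#' are excluded from the mean; parcels whose voxels are all NaN (or that have
#' no voxels) are flagged and returned as `NA`.
#'
#' @param intensity 3D numeric array, or an `RNifti` image.
#' @param labels 3D integer label array on the same grid, or an `RNifti`
#'   image.
#' @param intensity_affine,label_affine optional 4x4 affines; taken from the
#'   images when available, and required to agree within `1e-6`.
#' @return named numeric vector ordered by label value, with attribute
#'   `missing` listing flagged labels.
#' @export
parcellate_volume <- function(intensity, labels,
                              intensity_affine = NULL, label_affine = NULL) {
  grab_affine <- function(img, given) {
    if (!is.null(given)) return(given)
    xf <- tryCatch(RNifti::xform(img), error = function(e) NULL)
    if (!is.null(xf)) unclass(xf) else NULL
  }
  ia <- grab_affine(intensity, intensity_affine)
  la <- grab_affine(labels, label_affine)
  intensity <- as.array(intensity)
  labels <- as.array(labels)
  if (!identical(dim(intensity), dim(labels))) {
    stop_invalid("intensity and label volumes have different shapes")
  }
  if (!is.null(ia) && !is.null(la) && max(abs(ia - la)) > 1e-6) {
    stop_invalid("intensity and label volumes have different affines")
  }
  lab <- as.integer(round(labels))
  keep <- lab > 0L
  if (!any(keep)) stop_invalid("label volume contains only background")
  lab <- lab[keep]
  val <- as.numeric(intensity)[keep]
  ok <- is.finite(val)
  all_labels <- sort(unique(lab))
  sums <- tapply(ifelse(ok, val, 0), factor(lab, levels = all_labels), sum)
  ns <- tapply(as.numeric(ok), factor(lab, levels = all_labels), sum)
  out <- as.vector(sums) / ifelse(as.vector(ns) > 0, as.vector(ns), NA)
  names(out) <- as.character(all_labels)
  attr(out, "missing") <- names(out)[!is.finite(out)]
  out
}

#' Bundle a single tracer study
#'
#' @param molecule molecule name.
#' @param map region-value vector.
#' @param n_subjects number of subjects in the study (averaging weight, >= 1).
#' @return a `tracer_study`.
#' @export
tracer_study <- function(molecule, map, n_subjects = 1) {
  if (n_subjects < 1) stop_invalid("n_subjects must be >= 1")
  structure(list(molecule = molecule, map = as.numeric(map),
                 n_subjects = n_subjects),
            class = "tracer_study")
}

#' Assemble tracer studies into a density panel
#'
#' Molecules covered by several studies are combined by a weighted average
#' with study sample sizes as weights: `sum(n_i * map_i) / sum(n_i)`.
#' Molecule order is fixed by first appearance.
#'
#' @param studies list of [tracer_study()].
#' @param region_ids optional region identifiers.
#' @param compartment compartment tag, recycled per region.
#' @return a [density_panel()] (not z-scored).
#' @export
assemble_panel <- function(studies, region_ids = NULL,
                           compartment = "cortical") {
  if (!length(studies)) stop_invalid("no studies supplied")
  lens <- vapply(studies, function(s) length(s$map), 0L)
  if (length(unique(lens)) != 1L) {
    stop_invalid("all study maps must have the same length")
  }
  mols <- unique(vapply(studies, `[[`, "", "molecule"))
  cols <- lapply(mols, function(m) {
    sub <- studies[vapply(studies, `[[`, "", "molecule") == m]
    w <- vapply(sub, `[[`, 0, "n_subjects")
    if (sum(w) <= 0) stop_invalid("zero total weight for molecule %s", m)
    maps <- do.call(cbind, lapply(sub, `[[`, "map"))
    drop(maps %*% (w / sum(w)))
  })
  density_panel(do.call(cbind, cols), molecules = mols,
                region_ids = region_ids, compartment = compartment)
}

#' Z-score a density panel per molecule within a scope
#'
#' Columns are centred and scaled (sample standard deviation, `ddof = 1`)
#' over the rows belonging to `scope`; rows outside the scope are left
#' untouched. The scope is recorded on the panel.
#'
#' @param panel a [density_panel()].
#' @param scope `"joint"` (all rows), `"cortical"`, or `"subcortical"`.
#' @return the z-scored [density_panel()].
#' @export
zscore_panel <- function(panel, scope = c("joint", "cortical",
                                          "subcortical")) {
  scope <- match.arg(scope)
  rows <- if (scope == "joint") seq_len(nrow(panel$values)) else
    which(panel$compartment == scope)
  if (!length(rows)) stop_invalid("no rows in scope '%s'", scope)
  v <- panel$values
  for (j in seq_len(ncol(v))) {
    s <- stats::sd(v[rows, j])
    if (!is.finite(s) || s == 0) {
      stop_invalid("molecule %s has zero variance within scope '%s'",
                   panel$molecules[j], scope)
    }
    v[rows, j] <- (v[rows, j] - mean(v[rows, j])) / s
  }
  density_panel(v, molecules = panel$molecules, region_ids = panel$region_ids,
                compartment = panel$compartment, zscored = TRUE,
                zscore_scope = scope)
}

sidecar_path <- function(path) paste0(path, ".json")

#' Write a matrix (or panel) as TSV with a JSON sidecar
#'
#' Values are written in full precision (`%.17g`); the sidecar records row and
#' column identifiers, the matrix kind, and provenance.
#'
#' @param x a [similarity_matrix()], [density_panel()], or plain matrix.
#' @param path output TSV path; the sidecar goes to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path) {
  meta <- list(package = "receptome",
               version = as.character(utils::packageVersion("receptome")))
  if (inherits(x, "density_panel")) {
    m <- x$values
    meta <- c(meta, list(type = "density_panel", molecules = x$molecules,
                         region_ids = x$region_ids,
                         compartment = x$compartment, zscored = x$zscored,
                         zscore_scope = x$zscore_scope))
  } else {
    m <- as.matrix(x)
    meta <- c(meta, list(type = "similarity_matrix",
                         kind = sm_kind(x),
                         symmetric = isTRUE(attr(x, "symmetric")),
                         row_ids = rownames(m) %||%
                           sprintf("region_%03d", seq_len(nrow(m))),
                         col_ids = colnames(m) %||%
                           sprintf("col_%03d", seq_len(ncol(m)))))
  }
  lines <- apply(m, 1, function(r) paste(sprintf("%.17g", r),
                                         collapse = "\t"))
  writeLines(lines, path)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a matrix written by [write_matrix()]
#'
#' Round-trips values to better than `1e-12`. A missing sidecar produces a
#' warning and auto-generated identifiers; ragged rows and non-numeric cells
#' are parse errors naming the offending line.
#'
#' @param path TSV path.
#' @return a [similarity_matrix()] or [density_panel()] depending on the
#'   sidecar.
#' @export
read_matrix <- function(path) {
  lines <- readLines(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(fields)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1])[1]
    stop_invalid("ragged row at line %d (%d fields, expected %d)",
                 bad, widths[bad], widths[1])
  }
  m <- matrix(NA_real_, length(fields), widths[1])
  for (i in seq_along(fields)) {
    v <- suppressWarnings(as.numeric(fields[[i]]))
    if (anyNA(v)) stop_invalid("non-numeric cell at line %d", i)
    m[i, ] <- v
  }
  sc <- sidecar_path(path)
  if (!file.exists(sc)) {
    warning("missing sidecar for ", path, "; identifiers auto-generated",
            call. = FALSE)
    return(similarity_matrix(m, kind = "cross", symmetric = FALSE))
  }
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (identical(meta$type, "density_panel")) {
    density_panel(m, molecules = meta$molecules,
                  region_ids = meta$region_ids,
                  compartment = meta$compartment,
                  zscored = isTRUE(meta$zscored),
                  zscore_scope = meta$zscore_scope)
  } else {
    similarity_matrix(m, row_ids = meta$row_ids, col_ids = meta$col_ids,
                      kind = meta$kind %||% "cross",
                      symmetric = isTRUE(meta$symmetric))
  }
}
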