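# Lightweight S3 containers used throughout the package.

#' Construct a similarity matrix object
#'
#' A `similarity_matrix` is a plain numeric matrix carrying region identifiers
#' and a `kind` tag. Square receptomes are symmetric with unit diagonal and
#' entries in `[-1, 1]`; affinity matrices are symmetric with entries in
#' `[0, 1]`; FC/SC/MPC matrices host the corresponding modality.
#'
#' @param values numeric matrix (`n_a x n_b`).
#' @param row_ids,col_ids character identifiers; defaults are generated.
#' @param kind one of `"receptome"`, `"FC"`, `"SC"`, `"MPC"`, `"affinity"`,
#'   `"cross"`.
#' @param symmetric logical; checked when `TRUE`.
#' @return a `similarity_matrix` (a classed numeric matrix).
#' @export
similarity_matrix <- function(values,
                              row_ids = NULL,
                              col_ids = NULL,
                              kind = c("receptome", "FC", "SC", "MPC",
                                       "affinity", "cross"),
                              symmetric = NULL) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  row_ids <- row_ids %||% rownames(values) %||%
    sprintf("region_%03d", seq_len(nrow(values)))
  col_ids <- col_ids %||% colnames(values) %||%
    if (ncol(values) == nrow(values) && kind != "cross") row_ids else
      sprintf("col_%03d", seq_len(ncol(values)))
  rownames(values) <- row_ids
  colnames(values) <- col_ids
  if (is.null(symmetric)) {
    symmetric <- nrow(values) == ncol(values) &&
      max(abs(values - t(values))) < 1e-10
  }
  if (symmetric) check_square_symmetric(unclass(values), what = kind)
  if (kind == "receptome" && symmetric) {
    if (max(abs(diag(values) - 1)) > 1e-9) {
      stop_invalid("receptome diagonal must be exactly 1")
    }
    if (min(values) < -1 - 1e-9 || max(values) > 1 + 1e-9) {
      stop_invalid("receptome entries must lie in [-1, 1]")
    }
  }
  if (kind == "affinity") {
    if (min(values) < -1e-9 || max(values) > 1 + 1e-9) {
      stop_invalid("affinity entries must lie in [0, 1]")
    }
  }
  structure(values,
            kind = kind,
            symmetric = symmetric,
            class = c("similarity_matrix", "matrix", "array"))
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> kind=%s  %d x %d  symmetric=%s\n",
              attr(x, "kind"), nrow(x), ncol(x), attr(x, "symmetric")))
  invisible(x)
}

sm_kind <- function(m) attr(m, "kind") %||% "receptome"

#' Construct a density panel
#'
#' Region-by-molecule matrix of NTRM densities (receptor "fingerprints" along
#' rows), with molecule names, region identifiers, a per-region compartment
#' tag and the z-scoring state.
#'
#' @param values numeric `n_regions x n_molecules` matrix.
#' @param molecules character vector of molecule names.
#' @param region_ids character region identifiers.
#' @param compartment `"cortical"` or `"subcortical"`, recycled per region.
#' @param zscored logical; whether columns have been z-scored.
#' @param zscore_scope scope tag recorded by [zscore_panel()].
#' @return a `density_panel`.
#' @export
density_panel <- function(values, molecules = NULL, region_ids = NULL,
                          compartment = "cortical", zscored = FALSE,
                          zscore_scope = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (anyNA(values)) stop_invalid("density panel must not contain NA values")
  molecules <- molecules %||% colnames(values) %||%
    sprintf("mol%02d", seq_len(ncol(values)))
  region_ids <- region_ids %||% rownames(values) %||%
    sprintf("region_%03d", seq_len(nrow(values)))
  compartment <- rep_len(compartment, nrow(values))
  if (!all(compartment %in% c("cortical", "subcortical"))) {
    stop_invalid("compartment must be 'cortical' or 'subcortical'")
  }
  dimnames(values) <- list(region_ids, molecules)
  structure(list(values = values, molecules = molecules,
                 region_ids = region_ids, compartment = compartment,
                 zscored = zscored, zscore_scope = zscore_scope),
            class = "density_panel")
}

#' @export
print.density_panel <- function(x, ...) {
  cat(sprintf("<density_panel> %d regions x %d molecules (%s)%s\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$compartment), collapse = "+"),
              if (x$zscored) sprintf(", z-scored [%s]", x$zscore_scope) else ""))
  invisible(x)
}

#' Construct a geometry object
#'
#' Node coordinates (unit sphere for cortical-like geometries, millimetres for
#' volumetric ones), a symmetric zero-diagonal distance matrix, hemisphere
#' labels and a medial-wall mask.
#'
#' @param coords `n x 3` coordinate matrix.
#' @param dist `n x n` nonnegative symmetric distances.
#' @param hemisphere per-node label in `c("L", "R")`.
#' @param medial_mask per-node logical.
#' @return a `geometry`.
#' @export
geometry <- function(coords, dist, hemisphere, medial_mask = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  check_square_symmetric(dist, what = "distance matrix")
  if (nrow(dist) != n) stop_invalid("coords and dist disagree on n")
  if (any(diag(dist) != 0)) stop_invalid("distance diagonal must be zero")
  if (min(dist) < 0) stop_invalid("distances must be nonnegative")
  medial_mask <- medial_mask %||% rep(FALSE, n)
  structure(list(coords = coords, dist = dist,
                 hemisphere = hemisphere, medial_mask = medial_mask,
                 n_nodes = n),
            class = "geometry")
}

#' @export
print.geometry <- function(x, ...) {
  cat(sprintf("<geometry> %d nodes (L=%d, R=%d), %d medial\n", x$n_nodes,
              sum(x$hemisphere == "L"), sum(x$hemisphere == "R"),
              sum(x$medial_mask)))
  invisible(x)
}

is_unit_sphere <- function(geom, tol = 1e-6) {
  all(abs(sqrt(rowSums(geom$coords^2)) - 1) < tol)
}
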