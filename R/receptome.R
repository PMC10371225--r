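# Receptome construction: interregional Spearman similarity of receptor
# fingerprints, and gradient-fingerprint correlations.

#' Build the receptome from a z-scored density panel
#'
#' Entry (i, j) is the Spearman rank correlation (average ranks for ties)
#' between the NTRM fingerprints of regions i and j. The diagonal is exactly
#' 1. The receptome is the region-by-region matrix of interregional
#' chemoarchitectural similarity.
#'
#' @param panel a z-scored [density_panel()] with at least 3 molecules.
#' @return a symmetric [similarity_matrix()] of kind `"receptome"`.
#' @export
build_receptome <- function(panel) {
  if (!panel$zscored) stop_invalid("panel must be z-scored first")
  if (ncol(panel$values) < 3) stop_invalid("need at least 3 molecules")
  sds <- apply(panel$values, 1, stats::sd)
  if (any(sds == 0)) {
    stop_invalid("constant fingerprint for region(s): %s",
                 paste(panel$region_ids[sds == 0], collapse = ", "))
  }
  R <- stats::cor(t(panel$values), method = "spearman")
  diag(R) <- 1
  R <- (R + t(R)) / 2
  similarity_matrix(R, row_ids = panel$region_ids, kind = "receptome")
}

#' Cross-compartment receptome between two panels
#'
#' Rectangular Spearman similarity between the fingerprints of two panels
#' (e.g. subcortical voxels vs cortical parcels), each z-scored within its own
#' scope. Molecule sets and order must match exactly.
#'
#' @param panel_a,panel_b z-scored [density_panel()] objects with identical
#'   molecule ordering.
#' @return a rectangular [similarity_matrix()] of kind `"cross"`.
#' @export
build_cross_receptome <- function(panel_a, panel_b) {
  if (!identical(panel_a$molecules, panel_b$molecules)) {
    stop_invalid("panels must share the same molecules in the same order")
  }
  if (!panel_a$zscored || !panel_b$zscored) {
    stop_invalid("both panels must be z-scored")
  }
  X <- stats::cor(t(panel_a$values), t(panel_b$values), method = "spearman")
  similarity_matrix(X, row_ids = panel_a$region_ids,
                    col_ids = panel_b$region_ids, kind = "cross",
                    symmetric = FALSE)
}

#' Correlate a gradient with every molecule's density map
#'
#' Spearman correlation between a gradient (one value per region) and each
#' molecule column of the panel, with a two-sided significance test against a
#' spatial-autocorrelation-preserving null ensemble of the gradient.
#'
#' @param panel a [density_panel()] with `n_regions` rows.
#' @param gradient node-value vector of length `n_regions`.
#' @param nulls a [null_ensemble()] of surrogates for `gradient`.
#' @param alpha significance level for the `significant` flag.
#' @return data.frame with columns `molecule`, `rho`, `p`, `significant`.
#' @export
correlate_fingerprints_with_gradient <- function(panel, gradient, nulls,
                                                 alpha = 0.05) {
  if (length(gradient) != nrow(panel$values)) {
    stop_invalid("gradient length (%d) must equal n_regions (%d)",
                 length(gradient), nrow(panel$values))
  }
  out <- lapply(seq_len(ncol(panel$values)), function(j) {
    col <- panel$values[, j]
    tst <- association_test(gradient, col, nulls)
    data.frame(molecule = panel$molecules[j], rho = tst$rho, p = tst$p)
  })
  res <- do.call(rbind, out)
  res$significant <- res$p < alpha
  rownames(res) <- NULL
  res
}
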