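# Diffusion-map gradients: row thresholding, normalized-angle affinity,
# anisotropic diffusion embedding, alignment, and component significance.

#' Row-wise percentile sparsification
#'
#' For every row, entries below that row's `pct`-th percentile (computed over
#' off-diagonal entries, quantile type 7; ties at the threshold are all kept)
#' are set to 0; retained entries keep their signed values. The diagonal is
#' excluded from the percentile computation and zeroed. The resulting
#' (generally asymmetric) sparse matrix feeds the row-profile affinity kernel,
#' which restores symmetry.
#'
#' @param matrix a [similarity_matrix()] (square or rectangular).
#' @param pct percentile in `[0, 100)`; default 90 keeps the top 10% of each
#'   row.
#' @return a thresholded [similarity_matrix()] (kind `"cross"`, asymmetric).
#' @export
threshold_rows <- function(matrix, pct = 90) {
  if (pct < 0 || pct >= 100) stop_invalid("pct must be in [0, 100)")
  m <- as.matrix(matrix)
  square <- nrow(m) == ncol(m) &&
    identical(rownames(m), colnames(m))
  out <- m
  for (i in seq_len(nrow(m))) {
    row <- m[i, ]
    off <- if (square) row[-i] else row
    q <- stats::quantile(off, probs = pct / 100, type = 7, names = FALSE)
    keep <- row >= q
    out[i, !keep] <- 0
    if (square) out[i, i] <- 0
    if (all(out[i, ] == 0)) {
      stop_invalid("row %d is all zero after thresholding", i)
    }
  }
  similarity_matrix(out, row_ids = rownames(m), col_ids = colnames(m),
                    kind = "cross", symmetric = FALSE)
}

#' Normalized-angle affinity between row profiles
#'
#' `affinity(i, j) = 1 - acos(cosine(row_i, row_j)) / pi`: 1 for identical
#' rows, 0.5 for orthogonal rows, 0 for anti-parallel rows. Produces the
#' square nonnegative affinity matrix that diffusion embedding consumes.
#'
#' @param matrix a [similarity_matrix()] with no all-zero rows.
#' @return a symmetric [similarity_matrix()] of kind `"affinity"` with unit
#'   diagonal and entries in `[0, 1]`.
#' @export
normalized_angle_affinity <- function(matrix) {
  m <- as.matrix(matrix)
  norms <- sqrt(rowSums(m^2))
  if (any(norms == 0)) {
    stop_invalid("zero-norm row(s): %s",
                 paste(which(norms == 0), collapse = ", "))
  }
  cosine <- tcrossprod(m / norms)
  cosine <- pmin(pmax(cosine, -1), 1)
  aff <- 1 - acos(cosine) / pi
  aff <- (aff + t(aff)) / 2
  diag(aff) <- 1
  similarity_matrix(aff, row_ids = rownames(m), kind = "affinity")
}

# connectivity check on the support graph of a nonnegative matrix
assert_connected <- function(W) {
  n <- nrow(W)
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    i <- queue[1L]
    queue <- queue[-1L]
    nb <- which(W[i, ] > 0 & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  if (!all(seen)) {
    stop_invalid("affinity graph is disconnected (e.g. nodes %s unreachable)",
                 paste(utils::head(which(!seen), 5), collapse = ", "))
  }
}

#' Diffusion-map embedding of an affinity matrix
#'
#' Anisotropic normalization `W' = W / (d_i^alpha d_j^alpha)` (alpha = 0.5
#' retains global relations and is robust to noise; alpha = 0 reduces to the
#' plain Laplacian eigenmap normalization, alpha = 1 removes the sampling
#' density entirely), row normalization to a Markov operator, and
#' eigendecomposition through the symmetric conjugate. The trivial constant
#' eigenvector is dropped; components use the diffusion-time-0 convention and
#' are scaled by `lambda / (1 - lambda)`. The relative-variance fraction of a
#' component is its share of the retained (scaled) eigenvalue mass. Component
#' signs are fixed so that the node with the largest absolute value is
#' positive.
#'
#' @param affinity symmetric nonnegative connected [similarity_matrix()].
#' @param alpha anisotropy parameter in `[0, 1]`; default 0.5.
#' @param n_components number of non-trivial components to retain.
#' @return a `gradient_set`: list with `components` (n x k), `eigenvalues`
#'   (scaled, non-increasing), `variance_fraction` (sums to 1), `alpha`,
#'   `kernel`.
#' @export
diffusion_embedding <- function(affinity, alpha = 0.5, n_components = 10L) {
  W <- as.matrix(affinity)
  check_square_symmetric(W, tol = 1e-8, what = "affinity")
  if (min(W) < -1e-12) stop_invalid("affinity must be nonnegative")
  W <- (W + t(W)) / 2
  assert_connected(W)
  n <- nrow(W)
  d <- rowSums(W)
  W1 <- W / outer(d^alpha, d^alpha)
  d1 <- rowSums(W1)
  S <- W1 / outer(sqrt(d1), sqrt(d1))
  S <- (S + t(S)) / 2
  eig <- eigen(S, symmetric = TRUE)
  k <- min(n_components, n - 1L)
  if (k < 1) stop_invalid("need at least 2 nodes")
  v0 <- eig$vectors[, 1]
  psi <- eig$vectors / v0      # mapalign convention: divide by trivial vector
  lam <- eig$values[seq(2, k + 1)]
  lam <- pmin(lam, 1 - 1e-12)
  scaled <- pmax(lam / (1 - lam), 0)
  comps <- psi[, seq(2, k + 1), drop = FALSE] *
    rep(scaled, each = n)
  for (j in seq_len(k)) {
    if (comps[which.max(abs(comps[, j])), j] < 0) comps[, j] <- -comps[, j]
  }
  rownames(comps) <- rownames(W)
  colnames(comps) <- sprintf("G%d", seq_len(k))
  vf <- if (sum(scaled) > 0) scaled / sum(scaled) else rep(NA_real_, k)
  structure(list(components = comps, eigenvalues = scaled,
                 variance_fraction = vf, alpha = alpha,
                 threshold_pct = attr(affinity, "threshold_pct"),
                 kernel = "normalized_angle"),
            class = "gradient_set")
}

#' @export
print.gradient_set <- function(x, ...) {
  cat(sprintf("<gradient_set> %d regions x %d components; var%% = %s\n",
              nrow(x$components), ncol(x$components),
              paste(sprintf("%.1f", 100 * utils::head(x$variance_fraction, 5)),
                    collapse = ", ")))
  invisible(x)
}

#' Threshold, kernel, and embed in one call
#'
#' Convenience wrapper running [threshold_rows()], then
#' [normalized_angle_affinity()], then [diffusion_embedding()] -- the standard
#' route from a similarity matrix to its gradients.
#'
#' @inheritParams diffusion_embedding
#' @param matrix square [similarity_matrix()].
#' @param threshold_pct row sparsification percentile (default 90).
#' @return a `gradient_set`.
#' @export
compute_gradients <- function(matrix, threshold_pct = 90, alpha = 0.5,
                              n_components = 10L) {
  thr <- threshold_rows(matrix, pct = threshold_pct)
  aff <- normalized_angle_affinity(thr)
  gs <- diffusion_embedding(aff, alpha = alpha, n_components = n_components)
  gs$threshold_pct <- threshold_pct
  gs
}

#' Significance of gradient variance fractions against randomized panels
#'
#' Each molecule map is randomized with variogram-matching surrogates, the
#' receptome is rebuilt and re-embedded, and the observed relative-variance
#' fraction of each component is compared with the surrogate distribution:
#' `p_i = (1 + #{null_i >= observed_i}) / (n_valid + 1)`. Surrogate panels
#' that degenerate (zero-variance column, all-zero row) are skipped and
#' counted.
#'
#' @param panel a [density_panel()] (raw or z-scored; z-scoring is re-applied
#'   per surrogate).
#' @param geom the [geometry()] the panel lives on (drives the surrogates).
#' @param n_null number of surrogate panels (>= 1).
#' @param seed RNG seed.
#' @param threshold_pct,alpha,n_components embedding parameters.
#' @return list with `p` (per component), `observed` variance fractions,
#'   `null` (matrix of surrogate variance fractions), `n_skipped`.
#' @export
component_significance <- function(panel, geom, n_null = 1000L, seed = 1L,
                                   threshold_pct = 90, alpha = 0.5,
                                   n_components = 10L) {
  if (n_null < 1) stop_invalid("n_null must be >= 1")
  pz <- if (panel$zscored) panel else zscore_panel(panel, "joint")
  obs <- compute_gradients(build_receptome(pz), threshold_pct, alpha,
                           n_components)$variance_fraction
  n_mol <- ncol(panel$values)
  surr <- lapply(seq_len(n_mol), function(j) {
    vgm_surrogates(panel$values[, j], geom$dist, n_null = n_null,
                   seed = derive_seed(seed, j))$surrogates
  })
  k <- length(obs)
  nulls <- matrix(NA_real_, n_null, k)
  skipped <- 0L
  for (s in seq_len(n_null)) {
    vals <- vapply(surr, function(m) m[s, ], numeric(geom$n_nodes))
    res <- tryCatch({
      p_s <- zscore_panel(density_panel(vals, molecules = panel$molecules,
                                        region_ids = panel$region_ids),
                          "joint")
      compute_gradients(build_receptome(p_s), threshold_pct, alpha,
                        n_components)$variance_fraction
    }, error = function(e) NULL)
    if (is.null(res)) skipped <- skipped + 1L else nulls[s, ] <- res[seq_len(k)]
  }
  valid <- which(stats::complete.cases(nulls))
  p <- vapply(seq_len(k), function(i) {
    (1 + sum(nulls[valid, i] >= obs[i])) / (length(valid) + 1)
  }, 0)
  list(p = p, observed = obs, null = nulls[valid, , drop = FALSE],
       n_skipped = skipped)
}

#' Procrustes alignment of one gradient set to a reference
#'
#' Finds the orthogonal transform (rotation/reflection, no scaling)
#' minimizing the Frobenius distance between the target components and the
#' reference, and applies it to the target. Used e.g. to align
#' hemisphere-wise gradients before concatenation.
#'
#' @param reference,target `gradient_set` objects with the same number of
#'   components.
#' @return the aligned target `gradient_set`.
#' @export
align_procrustes <- function(reference, target) {
  A <- target$components
  B <- reference$components
  if (ncol(A) != ncol(B)) stop_invalid("component counts differ")
  sv <- svd(crossprod(A, B))
  Q <- sv$u %*% t(sv$v)
  out <- target
  out$components <- A %*% Q
  dimnames(out$components) <- dimnames(B)
  out
}

#' Diffusion embedding of a rectangular cross-similarity matrix
#'
#' The affinity is built over the row profiles of the (row-thresholded) cross
#' matrix and embedded as in [diffusion_embedding()]; column values are then
#' obtained by an affinity-weighted projection: each column takes the
#' weighted average of the row components, weighted by the column's positive
#' thresholded cross-similarities.
#'
#' @param cross rectangular [similarity_matrix()] (rows x columns).
#' @param alpha,n_components,threshold_pct embedding parameters.
#' @return list with `rows` (a `gradient_set` over the row compartment) and
#'   `cols` (a matrix of projected component values over the columns).
#' @export
embed_rectangular <- function(cross, alpha = 0.5, n_components = 10L,
                              threshold_pct = 90) {
  thr <- threshold_rows(cross, pct = threshold_pct)
  aff <- normalized_angle_affinity(thr)
  gs <- diffusion_embedding(aff, alpha = alpha, n_components = n_components)
  gs$threshold_pct <- threshold_pct
  W <- pmax(as.matrix(thr), 0)
  cw <- colSums(W)
  if (any(cw == 0)) {
    warning("columns with no positive suprathreshold similarity: ",
            paste(utils::head(which(cw == 0), 5), collapse = ", "),
            call. = FALSE)
  }
  proj <- t(W) %*% gs$components / ifelse(cw > 0, cw, NA)
  rownames(proj) <- colnames(cross)
  list(rows = gs, cols = proj)
}
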