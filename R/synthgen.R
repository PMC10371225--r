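# Synthetic-data generators.
#
# These emulate the statistical structure the analysis assumes -- spatially
# autocorrelated molecule density maps with planted low-dimensional gradients,
# signed similarity matrices with planted communities, and subject stacks of
# FC/SC/MPC-like matrices with distance-dependent edge structure -- so every
# downstream stage is testable without imaging data. They do not mimic PET
# tracer kinetics, partial-volume effects, or cortical folding.

#' Spherical parcel geometry from a Fibonacci lattice
#'
#' Places `n_nodes` near-uniform points on the unit sphere, applies a seeded
#' rotation about the x-axis (so different seeds give different lattices while
#' preserving the hemisphere split), splits hemispheres by the sign of x, and
#' computes great-circle distances.
#'
#' @param n_nodes number of parcels (>= 4).
#' @param seed RNG seed.
#' @param medial_frac fraction of nodes (those nearest the x = 0 midline)
#'   marked as medial wall; default 0.
#' @return a [geometry()].
#' @examples
#' g <- make_sphere_geometry(100, seed = 1)
#' range(g$dist)  # 0 .. pi
#' @export
make_sphere_geometry <- function(n_nodes, seed = 1L, medial_frac = 0) {
  if (n_nodes < 4) stop_invalid("n_nodes must be >= 4 (got %d)", n_nodes)
  i <- seq_len(n_nodes) - 1
  z <- 1 - 2 * (i + 0.5) / n_nodes
  r <- sqrt(pmax(0, 1 - z^2))
  theta <- pi * (3 - sqrt(5)) * i
  coords <- cbind(x = r * cos(theta), y = r * sin(theta), z = z)
  ang <- with_preserved_seed(seed, stats::runif(1, 0, 2 * pi))
  rot <- matrix(c(1, 0, 0,
                  0, cos(ang), -sin(ang),
                  0, sin(ang), cos(ang)), 3, 3, byrow = TRUE)
  coords <- coords %*% t(rot)
  coords <- coords / sqrt(rowSums(coords^2))
  gram <- pmin(pmax(tcrossprod(coords), -1), 1)
  d <- acos(gram)
  diag(d) <- 0
  d <- (d + t(d)) / 2
  hemi <- ifelse(coords[, 1] < 0, "L", "R")
  medial <- rep(FALSE, n_nodes)
  n_med <- round(medial_frac * n_nodes)
  if (n_med > 0) medial[order(abs(coords[, 1]))[seq_len(n_med)]] <- TRUE
  geometry(coords, d, hemi, medial)
}

# Cholesky factor of exp(-dist/length_scale) with escalating diagonal jitter.
chol_exp_cov <- function(dist, length_scale) {
  C <- exp(-dist / length_scale)
  for (jit in c(0, 1e-10, 1e-8, 1e-6, 1e-4)) {
    R <- tryCatch(chol(C + diag(jit, nrow(C))), error = function(e) NULL)
    if (!is.null(R)) return(R)
  }
  stop_invalid("covariance matrix is not positive definite even after jitter")
}

#' Spatially autocorrelated Gaussian random field on a geometry
#'
#' Draws from a zero-mean Gaussian field with covariance
#' `exp(-d / length_scale)` via Cholesky factorization of the (jittered)
#' covariance. Small `length_scale` approaches i.i.d. noise; large
#' `length_scale` approaches a constant map.
#'
#' @param geom a [geometry()].
#' @param length_scale correlation length, in the distance units of `geom`
#'   (> 0).
#' @param seed RNG seed.
#' @param n_maps number of independent maps; default 1 returns a vector.
#' @return numeric vector (or `n_nodes x n_maps` matrix).
#' @export
simulate_autocorrelated_map <- function(geom, length_scale, seed = 1L,
                                        n_maps = 1L) {
  if (length_scale <= 0) stop_invalid("length_scale must be > 0")
  R <- chol_exp_cov(geom$dist, length_scale)
  z <- with_preserved_seed(seed,
                           matrix(stats::rnorm(geom$n_nodes * n_maps),
                                  geom$n_nodes, n_maps))
  x <- crossprod(R, z)
  if (n_maps == 1L) drop(x) else x
}

#' Empirical variogram of a map over distance bins
#'
#' Half mean squared difference of values within equal-width distance bins.
#' @param values node values.
#' @param dist symmetric distance matrix.
#' @param n_bins number of equal-width bins over the pairwise distance range.
#' @param max_dist optional distance cutoff: only pairs at or below it enter
#'   the variogram (spatial autocorrelation is a short-range property; the
#'   flat sill carries no structure).
#' @return data.frame with bin midpoints, gamma (semivariance), and pair counts.
#' @export
empirical_variogram <- function(values, dist, n_bins = 25, max_dist = NULL) {
  ut <- upper.tri(dist)
  pd <- dist[ut]
  ii <- row(dist)[ut]; jj <- col(dist)[ut]
  if (!is.null(max_dist)) {
    keep <- pd <= max_dist
    pd <- pd[keep]; ii <- ii[keep]; jj <- jj[keep]
  }
  brks <- seq(0, max(pd), length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(pd, brks, rightmost.closed = TRUE), 1), n_bins)
  sq <- 0.5 * (values[ii] - values[jj])^2
  gamma <- as.vector(tapply(sq, factor(bin, levels = seq_len(n_bins)), mean))
  data.frame(mid = (brks[-1] + brks[-length(brks)]) / 2,
             gamma = gamma,
             n_pairs = tabulate(bin, n_bins))
}

#' Synthetic NTRM density panel with planted gradient axes
#'
#' Each molecule map is a linear combination of `n_axes` smooth, mutually
#' orthogonal latent spatial gradients (centred Gram-Schmidt of autocorrelated
#' fields) plus i.i.d. noise. The planted truth is returned for recovery tests.
#'
#' @param geom a [geometry()].
#' @param n_molecules number of molecule maps (>= `n_axes`); 19 mirrors the
#'   reference PET panel and reuses its molecule names.
#' @param n_axes number of planted latent gradients (>= 1).
#' @param noise_sd i.i.d. noise standard deviation (>= 0), expressed as a
#'   fraction of the unit-variance axes (loadings have unit scale, so this is
#'   approximately the noise fraction of a typical molecule's signal).
#' @param length_scale correlation length of the latent fields.
#' @param seed RNG seed.
#' @return list with `panel` (a [density_panel()]) and `truth` (planted axes,
#'   loadings).
#' @export
simulate_density_panel <- function(geom, n_molecules = 19L, n_axes = 3L,
                                   noise_sd = 0.1, length_scale = 0.5,
                                   seed = 1L) {
  if (noise_sd < 0) stop_invalid("noise_sd must be >= 0")
  if (n_axes < 1 || n_molecules < n_axes) {
    stop_invalid("need n_molecules >= n_axes >= 1")
  }
  n <- geom$n_nodes
  out <- with_preserved_seed(seed, {
    raw <- {
      R <- chol_exp_cov(geom$dist, length_scale)
      crossprod(R, matrix(stats::rnorm(n * n_axes), n, n_axes))
    }
    # centred Gram-Schmidt, unit-sd columns
    axes <- matrix(0, n, n_axes)
    for (k in seq_len(n_axes)) {
      v <- raw[, k] - mean(raw[, k])
      if (k > 1) {
        prev <- axes[, seq_len(k - 1), drop = FALSE]
        v <- v - prev %*% (crossprod(prev, v) / colSums(prev^2))
      }
      v <- v - mean(v)
      axes[, k] <- v / stats::sd(v)
    }
    loadings <- matrix(stats::rnorm(n_molecules * n_axes), n_molecules, n_axes)
    noise <- matrix(stats::rnorm(n * n_molecules, sd = noise_sd), n,
                    n_molecules)
    list(axes = axes, loadings = loadings,
         values = axes %*% t(loadings) + noise)
  })
  mols <- if (n_molecules <= 19L) ntrm_names()[seq_len(n_molecules)] else
    c(ntrm_names(), sprintf("mol%02d", 20:n_molecules))
  panel <- density_panel(out$values, molecules = mols,
                         region_ids = sprintf("region_%03d", seq_len(n)),
                         compartment = "cortical")
  truth <- structure(list(planted_axes = out$axes, loadings = out$loadings,
                          planted_partition = NULL, coupling_by_class = NULL),
                     class = "synth_truth")
  list(panel = panel, truth = truth)
}

#' Signed block matrix with planted communities
#'
#' Symmetric matrix with unit diagonal, `w_in` within planted blocks and
#' `w_out` between, plus symmetric Gaussian noise, clipped to `[-1, 1]`.
#' Fixture for signed community detection.
#'
#' @param n_nodes number of nodes.
#' @param n_blocks number of planted blocks (<= `n_nodes`).
#' @param w_in within-block weight (> 0).
#' @param w_out between-block weight (< 0).
#' @param noise_sd noise standard deviation.
#' @param seed RNG seed.
#' @return list with `matrix` (a [similarity_matrix()]) and `truth` holding the
#'   planted partition (0-based labels).
#' @export
simulate_signed_blocks <- function(n_nodes, n_blocks, w_in = 0.8,
                                   w_out = -0.4, noise_sd = 0.05, seed = 1L) {
  if (n_blocks > n_nodes) stop_invalid("n_blocks must be <= n_nodes")
  if (!(w_in > 0 && w_out < 0)) stop_invalid("need w_in > 0 > w_out")
  labels <- sort(rep_len(seq_len(n_blocks) - 1L, n_nodes))
  same <- outer(labels, labels, "==")
  W <- ifelse(same, w_in, w_out)
  if (noise_sd > 0) {
    E <- with_preserved_seed(seed,
                             matrix(stats::rnorm(n_nodes^2, sd = noise_sd),
                                    n_nodes, n_nodes))
    W <- W + (E + t(E)) / 2
  }
  W <- pmin(pmax(W, -1), 1)
  diag(W) <- 1
  truth <- structure(list(planted_axes = NULL, loadings = NULL,
                          planted_partition = labels,
                          coupling_by_class = NULL),
                     class = "synth_truth")
  list(matrix = similarity_matrix(W, kind = "receptome"), truth = truth)
}

#' Subject stacks of FC-, SC-, or MPC-like matrices
#'
#' Per-subject noisy realizations around a shared distance-dependent group
#' template. FC matrices are correlation-like (entries in `(-1, 1)` off the
#' unit diagonal); SC matrices are sparse nonnegative with edge probability
#' decaying in distance (so a naive consensus over-represents short edges);
#' MPC matrices are symmetric on a log-like scale.
#'
#' @param geom a [geometry()].
#' @param n_subjects number of subjects (>= 1).
#' @param kind `"FC"`, `"SC"`, or `"MPC"`.
#' @param seed RNG seed.
#' @return list of [similarity_matrix()], one per subject.
#' @export
simulate_subject_stack <- function(geom, n_subjects, kind = c("FC", "SC",
                                                              "MPC"),
                                   seed = 1L) {
  if (n_subjects < 1) stop_invalid("n_subjects must be >= 1")
  kind <- match.arg(kind)
  n <- geom$n_nodes
  D <- geom$dist
  with_preserved_seed(seed, {
    lapply(seq_len(n_subjects), function(s) {
      if (kind == "FC") {
        z <- 0.8 * exp(-D / 1.0)
        E <- matrix(stats::rnorm(n^2, sd = 0.1), n, n)
        z <- z + (E + t(E)) / 2
        r <- tanh(z)
        diag(r) <- 1
        similarity_matrix(r, kind = "FC")
      } else if (kind == "SC") {
        p <- exp(-D / 0.75)
        mask <- matrix(stats::runif(n^2) < p, n, n)
        mask[lower.tri(mask)] <- t(mask)[lower.tri(mask)]
        mu <- 50 * exp(-D / 0.5)
        w <- matrix(stats::rlnorm(n^2, meanlog = log(mu + 1e-12),
                                  sdlog = 0.5), n, n)
        w[lower.tri(w)] <- t(w)[lower.tri(w)]
        w <- w * mask
        diag(w) <- 0
        similarity_matrix(w, kind = "SC")
      } else {
        base <- 1.5 * exp(-D / 0.8)
        E <- matrix(stats::rnorm(n^2, sd = 0.1), n, n)
        m <- base + (E + t(E)) / 2
        diag(m) <- 0
        similarity_matrix(m, kind = "MPC")
      }
    })
  })
}

#' Paired matrices with planted class-wise row coupling
#'
#' Builds a smooth reference similarity matrix and a second matrix whose row
#' `i` is a noise-blended, rank-preserving copy of the reference row, with the
#' blend weight set per cytoarchitectural class so that the expected row-wise
#' Spearman coupling matches `coupling_by_class`. Fixture for class-comparison
#' power tests.
#'
#' @param geom a [geometry()].
#' @param class_labels per-node class labels (character or factor).
#' @param coupling_by_class named numeric vector of target couplings in
#'   `(0, 1)`, one per class.
#' @param seed RNG seed.
#' @return list with `reference`, `other` (both [similarity_matrix()]; `other`
#'   is row-wise planted and not symmetric), and `truth`.
#' @export
simulate_coupled_modalities <- function(geom, class_labels, coupling_by_class,
                                        seed = 1L) {
  cls <- as.character(class_labels)
  if (!all(unique(cls) %in% names(coupling_by_class))) {
    stop_invalid("coupling_by_class must name every class")
  }
  n <- geom$n_nodes
  with_preserved_seed(seed, {
    E <- matrix(stats::rnorm(n^2, sd = 0.05), n, n)
    A <- exp(-geom$dist / 0.7) + (E + t(E)) / 2
    A <- pmin(pmax((A + t(A)) / 2, -1), 1)
    diag(A) <- 1
    B <- matrix(0, n, n)
    for (i in seq_len(n)) {
      rho <- coupling_by_class[[cls[i]]]
      t_ratio <- rho / sqrt(1 - rho^2)
      w <- t_ratio / (1 + t_ratio)
      a <- scale(A[i, -i])[, 1]
      eps <- scale(stats::rnorm(n - 1))[, 1]
      B[i, -i] <- w * a + (1 - w) * eps
    }
    truth <- structure(list(planted_axes = NULL, loadings = NULL,
                            planted_partition = NULL,
                            coupling_by_class = coupling_by_class),
                       class = "synth_truth")
    list(reference = similarity_matrix(A, kind = "receptome"),
         other = similarity_matrix(B, kind = "cross", symmetric = FALSE),
         truth = truth)
  })
}
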