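# Spatial-autocorrelation-preserving surrogate maps and the association
# tests built on them. Naive permutation tests on spatially smooth brain maps
# inflate false positives; both generators here preserve the empirical
# autocorrelation structure of the input map.

#' Construct a null ensemble
#' @param surrogates `n_null x n_regions` surrogate values.
#' @param method `"vgm"` or `"spin"`.
#' @param seed seed used to generate the ensemble.
#' @param discarded optional `n_null x n_regions` logical marking entries
#'   invalidated by medial-wall rotation (spin only).
#' @param fits optional per-surrogate variogram fits (VGM only).
#' @return a `null_ensemble`.
#' @export
null_ensemble <- function(surrogates, method = c("vgm", "spin"), seed = NA,
                          discarded = NULL, fits = NULL) {
  method <- match.arg(method)
  surrogates <- as.matrix(surrogates)
  if (nrow(surrogates) < 1) stop_invalid("need at least one surrogate")
  structure(list(surrogates = surrogates, method = method, seed = seed,
                 discarded = discarded, fits = fits,
                 n_null = nrow(surrogates)),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("<null_ensemble> %d surrogates x %d regions (%s)\n",
              x$n_null, ncol(x$surrogates), x$method))
  invisible(x)
}

default_knn_grid <- function(n) {
  kmax <- floor(n / 4)
  if (kmax < 3) {
    stop_invalid("too few nodes (%d) for variogram matching (need >= 12)", n)
  }
  ks <- c(3, 5, 10 * 2^(0:12))
  unique(ks[ks <= kmax])
}

#' Variogram-matching surrogate maps
#'
#' Each surrogate randomly permutes the input map, smooths it with a
#' truncated-Gaussian k-nearest-neighbour kernel over a candidate `k` grid,
#' fits the empirical variogram of the smoothed permutation to that of the
#' original by least squares (`gamma_obs ~ beta * gamma_smooth + alpha`),
#' selects the `k` minimizing the residual sum of squares, and returns
#' `sqrt(beta) * smoothed + sqrt(alpha) * noise` (noise resampled from the
#' standardized original values), recentred to the original mean. This
#' recovers the spatial autocorrelation of the original map in each
#' permutation.
#'
#' @param map finite node values.
#' @param dist symmetric distance matrix.
#' @param n_null number of surrogates.
#' @param seed RNG seed.
#' @param knn_grid candidate neighbourhood sizes; default
#'   `{3, 5, 10, 20, 40, ...}` capped at `n/4`.
#' @param n_bins number of variogram distance bins (default 25).
#' @param vario_quantile the variogram is computed and fitted over pair
#'   distances up to this quantile (default 0.25): spatial autocorrelation
#'   lives at short range, and fitting the full range would weight the flat
#'   sill instead.
#' @return a [null_ensemble()] with per-surrogate `fits`
#'   (`k`, `beta`, `alpha`, `sse`).
#' @export
vgm_surrogates <- function(map, dist, n_null = 1000L, seed = 1L,
                           knn_grid = NULL, n_bins = 25L,
                           vario_quantile = 0.25) {
  if (!all(is.finite(map))) stop_invalid("map must be finite")
  check_square_symmetric(dist, what = "distance matrix")
  n <- length(map)
  if (nrow(dist) != n) stop_invalid("map/dist length mismatch")
  ks <- knn_grid %||% default_knn_grid(n)
  if (min(ks) > n - 1) stop_invalid("fewer nodes than smallest k")

  # precomputation shared by all surrogates
  ut <- upper.tri(dist)
  ii <- row(dist)[ut]; jj <- col(dist)[ut]
  pd <- dist[ut]
  dmax <- stats::quantile(pd, probs = vario_quantile, names = FALSE)
  short <- pd <= dmax
  ii <- ii[short]; jj <- jj[short]; pd <- pd[short]
  brks <- seq(0, max(pd), length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(pd, brks, rightmost.closed = TRUE), 1),
              n_bins)
  counts <- tabulate(bin, n_bins)
  vario_cols <- function(V) {
    # V: n x m matrix -> n_bins x m binned semivariogram (NA for empty bins)
    d2 <- 0.5 * (V[ii, , drop = FALSE] - V[jj, , drop = FALSE])^2
    rs <- rowsum(d2, bin)
    out <- matrix(NA_real_, n_bins, ncol(d2))
    out[as.integer(rownames(rs)), ] <- rs
    out / counts
  }
  obs <- drop(vario_cols(matrix(map, ncol = 1)))
  use_bins <- counts > 0
  smoothers <- lapply(ks, function(k) {
    W <- matrix(0, n, n)
    for (i in seq_len(n)) {
      ord <- order(dist[i, -i])
      nb <- seq_len(n)[-i][ord[seq_len(k)]]
      dk <- dist[i, nb[k]]
      w <- exp(-0.5 * (dist[i, nb] / dk)^2)
      W[i, nb] <- w / sum(w)
    }
    W
  })

  sd_map <- stats::sd(map)
  std_vals <- if (sd_map > 0) (map - mean(map)) / sd_map else rep(0, n)
  res <- with_preserved_seed(seed, {
    perms <- vapply(seq_len(n_null), function(s) map[sample.int(n)],
                    numeric(n))
    best_sse <- rep(Inf, n_null)
    best <- list(beta = numeric(n_null), alpha = numeric(n_null),
                 k = integer(n_null),
                 smoothed = matrix(0, n, n_null))
    for (kidx in seq_along(ks)) {
      sm <- smoothers[[kidx]] %*% perms
      vs <- vario_cols(sm)
      vs_u <- vs[use_bins, , drop = FALSE]
      obs_u <- obs[use_bins]
      mvs <- colMeans(vs_u)
      cov_so <- colMeans(vs_u * obs_u) - mvs * mean(obs_u)
      var_s <- colMeans(vs_u^2) - mvs^2
      beta <- ifelse(var_s > 0, cov_so / var_s, 0)
      beta <- pmax(beta, 0)
      alpha <- pmax(mean(obs_u) - beta * mvs, 0)
      fitted <- sweep(vs_u, 2, beta, "*")
      fitted <- sweep(fitted, 2, alpha, "+")
      sse <- colSums((fitted - obs_u)^2)
      better <- sse < best_sse
      if (any(better)) {
        best_sse[better] <- sse[better]
        best$beta[better] <- beta[better]
        best$alpha[better] <- alpha[better]
        best$k[better] <- ks[kidx]
        best$smoothed[, better] <- sm[, better]
      }
    }
    noise <- vapply(seq_len(n_null),
                    function(s) sample(std_vals, n, replace = TRUE),
                    numeric(n))
    surr <- sweep(best$smoothed, 2, sqrt(best$beta), "*") +
      sweep(noise, 2, sqrt(best$alpha), "*")
    surr <- sweep(surr, 2, colMeans(surr) - mean(map), "-")
    list(surr = t(surr), fits = data.frame(k = best$k, beta = best$beta,
                                           alpha = best$alpha,
                                           sse = best_sse))
  })
  null_ensemble(res$surr, method = "vgm", seed = seed, fits = res$fits)
}

# n_null uniform random rotation matrices from unit quaternions
random_rotations <- function(n_null) {
  q <- matrix(stats::rnorm(4 * n_null), n_null, 4)
  q <- q / sqrt(rowSums(q^2))
  lapply(seq_len(n_null), function(s) {
    a <- q[s, 1]; b <- q[s, 2]; c <- q[s, 3]; d <- q[s, 4]
    matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
             2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
             2 * (b * d - a * c), 2 * (c * d + a * b),
             a^2 - b^2 - c^2 + d^2),
           3, 3, byrow = TRUE)
  })
}

# Bijective nearest-available assignment: each target parcel receives the
# nearest rotated source parcel still unassigned; conflicts are won by the
# closer parcel, ties by lowest index. sim[i, j] = similarity of target i to
# rotated source j.
greedy_match <- function(sim) {
  n <- nrow(sim)
  assign_to <- integer(n)     # target i -> source
  free_t <- rep(TRUE, n)
  free_s <- rep(TRUE, n)
  while (any(free_t)) {
    ti <- which(free_t)
    si <- which(free_s)
    sub <- sim[ti, si, drop = FALSE]
    pick <- max.col(sub, ties.method = "first")
    want <- si[pick]
    # one winner per contested source: the target with highest similarity
    o <- order(sub[cbind(seq_along(ti), pick)], decreasing = TRUE)
    taken <- logical(length(si))
    for (r in o) {
      if (!taken[pick[r]]) {
        taken[pick[r]] <- TRUE
        assign_to[ti[r]] <- want[r]
        free_t[ti[r]] <- FALSE
        free_s[want[r]] <- FALSE
      }
    }
  }
  assign_to
}

#' Spin-permutation surrogate maps
#'
#' Applies a uniform random rotation to the left-hemisphere parcel
#' coordinates and its midline (x = 0) reflection to the right hemisphere,
#' then reassigns parcel values by a bijective nearest-available match within
#' each hemisphere, so each surrogate is an exact permutation of the original
#' values. Assignments involving the medial wall are marked discarded.
#' Requires unit-sphere geometry; volumetric inputs must use
#' [vgm_surrogates()].
#'
#' @param map node values.
#' @param geom unit-sphere [geometry()].
#' @param n_null number of surrogates.
#' @param seed RNG seed.
#' @param rotations optional list of 3x3 rotation matrices (overrides the
#'   random draws; used for deterministic checks).
#' @return a [null_ensemble()] with a `discarded` mask.
#' @export
spin_surrogates <- function(map, geom, n_null = 1000L, seed = 1L,
                            rotations = NULL) {
  if (!is_unit_sphere(geom)) {
    stop_invalid(paste("spin permutation requires unit-sphere geometry;",
                       "use vgm_surrogates() for volumetric data"))
  }
  n <- geom$n_nodes
  if (length(map) != n) stop_invalid("map/geometry length mismatch")
  mirror <- diag(c(-1, 1, 1))
  hemis <- list(L = which(geom$hemisphere == "L"),
                R = which(geom$hemisphere == "R"))
  rot_list <- if (!is.null(rotations)) rotations else
    with_preserved_seed(seed, random_rotations(n_null))
  n_null <- length(rot_list)
  surr <- matrix(NA_real_, n_null, n)
  disc <- matrix(FALSE, n_null, n)
  for (s in seq_len(n_null)) {
    Rl <- rot_list[[s]]
    Rr <- mirror %*% Rl %*% mirror
    for (h in c("L", "R")) {
      idx <- hemis[[h]]
      if (!length(idx)) next
      Rh <- if (h == "L") Rl else Rr
      rotated <- geom$coords[idx, , drop = FALSE] %*% t(Rh)
      sim <- geom$coords[idx, , drop = FALSE] %*% t(rotated)
      src <- greedy_match(sim)
      surr[s, idx] <- map[idx[src]]
      disc[s, idx] <- geom$medial_mask[idx] | geom$medial_mask[idx[src]]
    }
  }
  colnames(surr) <- names(map)
  null_ensemble(surr, method = "spin", seed = seed, discarded = disc)
}

#' Spearman association test against a surrogate ensemble
#'
#' `rho = Spearman(x, y)`; the two-sided p-value is
#' `(1 + #{|rho_null| >= |rho|}) / (n_null + 1)` where `rho_null` correlates
#' each surrogate of `x` with `y`. Entries discarded by the spin procedure
#' are dropped pairwise per surrogate.
#'
#' @param x,y node-value vectors of equal length.
#' @param nulls a [null_ensemble()] generated for `x`.
#' @return list with `rho`, `p`, `rho_null`.
#' @export
association_test <- function(x, y, nulls) {
  if (length(x) != length(y)) stop_invalid("x and y lengths differ")
  if (nulls$n_null < 1) stop_invalid("empty null ensemble")
  rho <- spearman(x, y)
  S <- nulls$surrogates
  if (is.null(nulls$discarded) || !any(nulls$discarded)) {
    ry <- rank(y)
    rS <- apply(S, 1, rank)        # n x n_null
    rho_null <- drop(stats::cor(rS, ry))
  } else {
    rho_null <- vapply(seq_len(nulls$n_null), function(s) {
      ok <- !nulls$discarded[s, ] & is.finite(S[s, ])
      if (sum(ok) < 3) return(NA_real_)
      spearman(S[s, ok], y[ok])
    }, 0)
  }
  list(rho = rho, p = surrogate_p(rho, rho_null), rho_null = rho_null)
}

#' Alignment of a gradient with labelled networks, against surrogates
#'
#' For each class, the statistic is the mean gradient value inside the class;
#' the two-sided p-value is the surrogate quantile of that statistic with the
#' +1 correction.
#'
#' @param gradient node values.
#' @param labels per-node class labels covering all nodes.
#' @param nulls a [null_ensemble()] for `gradient`.
#' @return data.frame with `class`, `statistic`, `p`.
#' @export
network_alignment_test <- function(gradient, labels, nulls) {
  labels <- as.character(labels)
  if (length(labels) != length(gradient)) {
    stop_invalid("labels must cover all nodes")
  }
  classes <- sort(unique(labels))
  out <- lapply(classes, function(cl) {
    idx <- which(labels == cl)
    if (length(idx) == 1) {
      warning("singleton class '", cl, "'", call. = FALSE)
    }
    obs <- mean(gradient[idx])
    null_stat <- vapply(seq_len(nulls$n_null), function(s) {
      ok <- idx
      if (!is.null(nulls$discarded)) ok <- idx[!nulls$discarded[s, idx]]
      if (!length(ok)) return(NA_real_)
      mean(nulls$surrogates[s, ok])
    }, 0)
    null_stat <- null_stat[is.finite(null_stat)]
    m <- length(null_stat)
    p_hi <- (1 + sum(null_stat >= obs)) / (m + 1)
    p_lo <- (1 + sum(null_stat <= obs)) / (m + 1)
    data.frame(class = cl, statistic = obs,
               p = min(1, 2 * min(p_hi, p_lo)))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
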