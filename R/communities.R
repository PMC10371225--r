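# Signed-network community detection, partition comparison, modular
# stability, and WPGMA hierarchical clustering.

#' Construct a partition
#' @param labels per-node community ids; relabelled to contiguous 0-based
#'   integers in order of first appearance.
#' @param gamma resolution parameter the partition was obtained at.
#' @param seed seed used by the optimizer.
#' @return a `partition`.
#' @export
partition <- function(labels, gamma = NA_real_, seed = NA) {
  labels <- as.integer(factor(labels, levels = unique(labels))) - 1L
  structure(list(labels = labels, gamma = gamma, seed = seed,
                 n_communities = length(unique(labels))),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("<partition> %d nodes, %d communities (gamma=%s)\n",
              length(x$labels), x$n_communities, format(x$gamma)))
  invisible(x)
}

part_labels <- function(p) if (inherits(p, "partition")) p$labels else
  as.integer(factor(p, levels = unique(p))) - 1L

# split a signed matrix into positive/negative parts with zero diagonal
signed_parts <- function(matrix) {
  W <- as.matrix(matrix)
  check_square_symmetric(W, what = "signed matrix")
  diag(W) <- 0
  if (all(W == 0)) stop_invalid("matrix has no off-diagonal weight")
  list(Wp = pmax(W, 0), Wn = pmax(-W, 0))
}

# Negative-asymmetric signed quality from pre-split parts. The null-model
# term k_i k_j / v sums over all pairs including i = j (standard modularity
# convention); observed weights exclude the diagonal (zeroed at entry).
signed_quality_parts <- function(Wp, Wn, labels, gamma) {
  vp <- sum(Wp); vn <- sum(Wn)
  lab <- factor(labels)
  q_one <- function(W, v) {
    if (v <= 0) return(0)
    k <- rowSums(W)
    Wc <- vapply(split(seq_along(labels), lab), function(idx) {
      sum(W[idx, idx])
    }, 0)
    Kc <- vapply(split(k, lab), sum, 0)
    (sum(Wc) - gamma * sum(Kc^2) / v) / v
  }
  qp <- q_one(Wp, vp)
  qn <- q_one(Wn, vn)
  if (vp + vn <= 0) return(0)
  qp - (vn / (vp + vn)) * qn
}

#' Negative-asymmetric signed modularity
#'
#' `Q* = Q+ - (v- / (v+ + v-)) * Q-`, where `Q+` and `Q-` are the
#' resolution-gamma modularities of the positive and negative sub-networks and
#' `v+`, `v-` their total weights: positive edge weight is maximized within
#' communities while negative weight is pushed between them, and the negative
#' term is down-weighted by its share of the total weight. The matrix
#' diagonal is excluded from the observed edge weights.
#'
#' @param matrix symmetric signed [similarity_matrix()].
#' @param partition a [partition()] or label vector.
#' @param gamma resolution parameter (scales the null-model term in both the
#'   positive and negative sub-networks).
#' @return the scalar quality `Q*`.
#' @export
signed_quality <- function(matrix, partition, gamma = 1) {
  parts <- signed_parts(matrix)
  signed_quality_parts(parts$Wp, parts$Wn, part_labels(partition), gamma)
}

# --- native Leiden-style optimizer for the signed quality ------------------

# One local-moving phase. Wp/Wn may carry self-loops (aggregated graphs);
# self-loops travel with their node and do not enter move gains.
# constraint, when given, restricts candidate communities to those inside the
# same constraint group (used by the refinement phase).
local_move <- function(Wp, Wn, labels, gamma, cp, cn, vp, vn,
                       constraint = NULL) {
  n <- nrow(Wp)
  kp <- rowSums(Wp); kn <- rowSums(Wn)
  repeat {
    moved <- FALSE
    for (i in sample.int(n)) {
      a <- labels[i]
      lab_f <- factor(labels)
      wp_i <- Wp[i, ]; wp_i[i] <- 0
      wn_i <- Wn[i, ]; wn_i[i] <- 0
      Sp <- vapply(split(wp_i, lab_f), sum, 0)
      Sn <- vapply(split(wn_i, lab_f), sum, 0)
      Kp <- vapply(split(kp, lab_f), sum, 0)
      Kn <- vapply(split(kn, lab_f), sum, 0)
      comms <- as.integer(levels(lab_f))
      self <- comms == a
      Kp[self] <- Kp[self] - kp[i]
      Kn[self] <- Kn[self] - kn[i]
      cand <- rep(TRUE, length(comms))
      if (!is.null(constraint)) {
        cand <- vapply(comms, function(cc) {
          any(constraint[labels == cc & seq_len(n) != i] == constraint[i]) ||
            cc == a
        }, TRUE)
      }
      gain <- cp * (2 * Sp - gamma * 2 * kp[i] * Kp / max(vp, 1e-300)) -
        cn * (2 * Sn - gamma * 2 * kn[i] * Kn / max(vn, 1e-300))
      gain[!cand] <- -Inf
      best <- which.max(gain)
      if (comms[best] != a && gain[best] > gain[self] + 1e-12) {
        labels[i] <- comms[best]
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  labels
}

aggregate_signed <- function(W, groups) {
  g <- factor(groups)
  t(rowsum(t(rowsum(W, g)), g))
}

#' Signed Leiden community detection
#'
#' Greedy optimization of the negative-asymmetric [signed_quality()] by
#' Leiden-style phases: local moving over seeded random node orders, a
#' refinement pass that rebuilds each community from singletons (moves
#' constrained to stay within the parent community), and aggregation of the
#' refined partition, repeated until the quality stops improving. The quality
#' never decreases across phases, and results are deterministic under a fixed
#' seed.
#'
#' @param matrix symmetric signed [similarity_matrix()].
#' @param gamma resolution parameter.
#' @param seed RNG seed.
#' @param max_levels safety cap on aggregation rounds.
#' @return a [partition()] with contiguous 0-based labels and the achieved
#'   quality in `$quality`.
#' @export
leiden_partition <- function(matrix, gamma = 1, seed = 1L, max_levels = 20L) {
  parts <- signed_parts(matrix)
  Wp0 <- parts$Wp; Wn0 <- parts$Wn
  n <- nrow(Wp0)
  vp <- sum(Wp0); vn <- sum(Wn0)
  cp <- if (vp > 0) 1 / vp else 0
  cn <- if (vp + vn > 0) 1 / (vp + vn) else 0
  base_labels <- with_preserved_seed(seed, {
    node2base <- seq_len(n)        # aggregate node -> representative mapping
    membership <- seq_len(n)       # base node -> aggregate node index
    Wp <- Wp0; Wn <- Wn0
    labels <- seq_len(nrow(Wp))
    q_prev <- -Inf
    for (lev in seq_len(max_levels)) {
      labels <- local_move(Wp, Wn, labels, gamma, cp, cn, vp, vn)
      base <- labels[membership]
      q_now <- signed_quality_parts(Wp0, Wn0, base, gamma)
      if (q_now <= q_prev + 1e-12) break
      q_prev <- q_now
      # refinement: singletons constrained to the parent communities
      refined <- local_move(Wp, Wn, seq_len(nrow(Wp)), gamma, cp, cn, vp, vn,
                            constraint = labels)
      refined <- as.integer(factor(refined, levels = unique(refined)))
      if (max(refined) == nrow(Wp)) {
        # no merges possible; stop at the current partition
        break
      }
      # aggregate refined groups; parent communities seed the next level
      parent <- vapply(split(labels, refined), function(x) x[1], 0)
      Wp <- aggregate_signed(Wp, refined)
      Wn <- aggregate_signed(Wn, refined)
      membership <- refined[membership]
      labels <- as.integer(parent)
      if (nrow(Wp) <= 1) break
    }
    labels[membership]
  })
  out <- partition(base_labels, gamma = gamma, seed = seed)
  out$quality <- signed_quality_parts(Wp0, Wn0, out$labels, gamma)
  out
}

#' z-scored Rand pair-counting similarity of two partitions
#'
#' The number of node pairs `w` co-assigned in both partitions is z-scored
#' against its mean and variance under the permutation (hypergeometric) null
#' with the published analytic variance, so that independent partitions score
#' near 0 and identical non-trivial partitions score highly. Symmetric in its
#' arguments.
#'
#' @param p,q partitions ([partition()] or label vectors) over the same
#'   nodes.
#' @return the z-rand score.
#' @export
zrand <- function(p, q) {
  lp <- part_labels(p); lq <- part_labels(q)
  if (length(lp) != length(lq)) stop_invalid("partition lengths differ")
  n <- length(lp)
  M <- n * (n - 1) / 2
  tab <- table(lp, lq)
  n1 <- rowSums(tab); n2 <- colSums(tab)
  ch2 <- function(x) x * (x - 1) / 2
  w <- sum(ch2(tab))
  M1 <- sum(ch2(n1)); M2 <- sum(ch2(n2))
  muw <- M1 * M2 / M
  C1 <- n * (n^2 - 3 * n - 2) - 8 * (n + 1) * M1 + 4 * sum(n1^3)
  C2 <- n * (n^2 - 3 * n - 2) - 8 * (n + 1) * M2 + 4 * sum(n2^3)
  a <- 4 * M1 - 2 * M
  b <- 4 * M2 - 2 * M
  varw <- M / 16 - (a^2 * b^2) / (256 * M^2) +
    C1 * C2 / (16 * n * (n - 1) * (n - 2)) +
    (a^2 - 4 * C1 - 4 * M) * (b^2 - 4 * C2 - 4 * M) /
      (64 * n * (n - 1) * (n - 2) * (n - 3))
  if (!is.finite(varw) || varw <= 0) return(0)
  (w - muw) / sqrt(varw)
}

#' Default resolution grids
#'
#' The cortical grid spans gamma 0.5-10 in steps of 0.05 (191 values); the
#' subcortical grid spans 1-10 in steps of 0.5 (19 values).
#' @return numeric vector of resolution parameters.
#' @export
gamma_grid_cortical <- function() seq(0.5, 10, by = 0.05)

#' @rdname gamma_grid_cortical
#' @export
gamma_grid_subcortical <- function() seq(1, 10, by = 0.5)

#' Partition ensembles across a resolution grid with z-rand consensus
#'
#' For each resolution, `n_reps` seeded Leiden runs are compared all-to-all
#' with [zrand()]; the consensus partition is the one with the highest mean
#' z-rand (highest similarity to all other partitions at that resolution;
#' ties broken by lowest run index), and the variance of pairwise z-rand
#' scores is recorded -- a high mean and low variance indicate a stable
#' partition solution.
#'
#' @param matrix symmetric signed [similarity_matrix()].
#' @param gamma_grid resolutions to sample (e.g. [gamma_grid_cortical()]).
#' @param n_reps partitions per resolution (>= 2).
#' @param seed master seed; per-run seeds are derived from it via a counter.
#' @return a `partition_ensemble`: per-resolution partitions, mean z-rand per
#'   partition, z-rand variance, and the consensus [partition()].
#' @export
partition_ensemble <- function(matrix, gamma_grid, n_reps = 100L, seed = 1L) {
  if (!length(gamma_grid)) stop_invalid("empty gamma grid")
  if (n_reps < 2) stop_invalid("n_reps must be >= 2")
  per_gamma <- lapply(seq_along(gamma_grid), function(gi) {
    g <- gamma_grid[gi]
    runs <- lapply(seq_len(n_reps), function(r) {
      leiden_partition(matrix, gamma = g,
                       seed = derive_seed(seed, gi * 100000 + r))
    })
    Z <- matrix(NA_real_, n_reps, n_reps)
    for (i in seq_len(n_reps - 1)) {
      for (j in seq(i + 1, n_reps)) {
        Z[i, j] <- Z[j, i] <- zrand(runs[[i]], runs[[j]])
      }
    }
    mean_z <- rowMeans(Z, na.rm = TRUE)
    consensus <- which.max(mean_z)   # ties -> lowest index
    list(gamma = g, partitions = runs, mean_zrand = mean_z,
         zrand_variance = stats::var(Z[upper.tri(Z)]),
         consensus = runs[[consensus]], consensus_index = consensus)
  })
  structure(list(gamma_grid = gamma_grid, per_gamma = per_gamma,
                 seed = seed, n_reps = n_reps),
            class = "partition_ensemble")
}

#' @export
print.partition_ensemble <- function(x, ...) {
  cat(sprintf("<partition_ensemble> %d resolutions x %d runs\n",
              length(x$gamma_grid), x$n_reps))
  invisible(x)
}

#' Modular stability of an ROI across resolutions
#'
#' `score = Cmax * (1 - Cin / Ctot) * s`, where `Cmax` is the largest
#' fraction of the ROI covered by one community, `Cin` the number of distinct
#' communities inside the ROI, `Ctot` the total number of communities at that
#' resolution, and `s` the ROI's share of all nodes. An ROI that stays
#' covered by a single community while the overall partition refines keeps a
#' high score; an ROI fragmented into every community scores 0.
#'
#' @param partitions_by_resolution list of [partition()] objects.
#' @param roi_mask logical or integer node subset (nonempty).
#' @param normalization `"multiply"` (the printed formula, default) or
#'   `"divide"` (divide by `s` instead; exposed because the score is
#'   described both ways).
#' @return data.frame with `gamma`, `cmax`, `cin`, `ctot`, `s`, `score` per
#'   resolution.
#' @export
modular_stability <- function(partitions_by_resolution, roi_mask,
                              normalization = c("multiply", "divide")) {
  normalization <- match.arg(normalization)
  out <- lapply(partitions_by_resolution, function(p) {
    labels <- part_labels(p)
    idx <- if (is.logical(roi_mask)) which(roi_mask) else as.integer(roi_mask)
    if (!length(idx)) stop_invalid("empty ROI")
    inside <- labels[idx]
    cmax <- max(table(inside)) / length(inside)
    cin <- length(unique(inside))
    ctot <- length(unique(labels))
    s <- length(idx) / length(labels)
    base <- cmax * (1 - cin / ctot)
    score <- if (normalization == "multiply") base * s else base / s
    data.frame(gamma = if (inherits(p, "partition")) p$gamma else NA_real_,
               cmax = cmax, cin = cin, ctot = ctot, s = s, score = score)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' WPGMA hierarchical clustering of fingerprint profiles
#'
#' Agglomerative clustering with Euclidean inter-point distances and the
#' WPGMA update `d(k, i+j) = (d(k, i) + d(k, j)) / 2`
#' (`stats::hclust(method = "mcquitty")`). Used e.g. on z-scored mean NTRM
#' density profiles of subcortical structures per hemisphere.
#'
#' @param features region-by-feature numeric matrix with >= 2 rows; row names
#'   are the leaf identifiers and must be unique.
#' @return an `hclust` dendrogram.
#' @export
wpgma_cluster <- function(features) {
  features <- as.matrix(features)
  if (nrow(features) < 2) stop_invalid("need at least 2 rows")
  ids <- rownames(features) %||% sprintf("leaf_%02d", seq_len(nrow(features)))
  if (anyDuplicated(ids)) stop_invalid("duplicate leaf ids")
  rownames(features) <- ids
  stats::hclust(stats::dist(features, method = "euclidean"),
                method = "mcquitty")
}
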