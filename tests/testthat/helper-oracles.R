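# Shared oracles and fixtures, independent of the package internals.

# all set partitions of n elements as restricted growth strings (rows)
enum_partitions <- function(n) {
  out <- list()
  recurse <- function(prefix, max_used) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (v in seq_len(max_used + 1)) {
      recurse(c(prefix, v), max(max_used, v))
    }
  }
  recurse(integer(0), 0L)
  do.call(rbind, out)
}

# brute-force negative-asymmetric signed quality by explicit edge sums
brute_signed_quality <- function(W, labels, gamma = 1) {
  W <- as.matrix(W)
  diag(W) <- 0
  Wp <- pmax(W, 0); Wn <- pmax(-W, 0)
  vp <- sum(Wp); vn <- sum(Wn)
  one <- function(A, v) {
    if (v <= 0) return(0)
    k <- rowSums(A)
    q <- 0
    n <- nrow(A)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (labels[i] == labels[j]) {
          obs <- if (i != j) A[i, j] else 0
          q <- q + obs - gamma * k[i] * k[j] / v
        }
      }
    }
    q / v
  }
  one(Wp, vp) - (vn / (vp + vn)) * one(Wn, vn)
}

# z-rand recomputed from explicit pair enumeration (mean/variance by the
# published hypergeometric moments, but w / M1 / M2 counted pair by pair)
brute_zrand <- function(lp, lq) {
  n <- length(lp)
  w <- 0; M1 <- 0; M2 <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      s1 <- lp[i] == lp[j]
      s2 <- lq[i] == lq[j]
      M1 <- M1 + s1
      M2 <- M2 + s2
      w <- w + (s1 && s2)
    }
  }
  list(w = w, M1 = M1, M2 = M2, mu = M1 * M2 / (n * (n - 1) / 2))
}

# naive per-row Spearman by explicit rank/Pearson computation
naive_row_spearman <- function(A, B) {
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    j <- setdiff(which(A[i, ] != 0 & B[i, ] != 0), i)
    ra <- rank(A[i, j]); rb <- rank(B[i, j])
    sum((ra - mean(ra)) * (rb - mean(rb))) /
      sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  }, 0)
}

# dense-eigensolver oracle for the diffusion embedding (independent algebra:
# eigendecompose the row-normalized Markov operator directly, non-symmetric)
oracle_diffusion <- function(W, alpha, k) {
  d <- rowSums(W)
  W1 <- W / outer(d^alpha, d^alpha)
  P <- W1 / rowSums(W1)
  e <- eigen(P)
  ord <- order(Re(e$values), decreasing = TRUE)
  vals <- Re(e$values)[ord]
  vecs <- Re(e$vectors)[, ord, drop = FALSE]
  # normalize like the trivial-vector division: psi_0 is constant for P
  psi <- vecs / vecs[, 1]
  lam <- pmin(vals[seq(2, k + 1)], 1 - 1e-12)
  scaled <- pmax(lam / (1 - lam), 0)
  comps <- psi[, seq(2, k + 1), drop = FALSE] * rep(scaled, each = nrow(W))
  list(values = scaled, components = comps)
}

# compare two embeddings component-wise up to sign and per-component scale
# (the trivial-eigenvector division fixes directions, not norms)
expect_embedding_match <- function(components, oracle_components,
                                   tol = 1e-8) {
  for (j in seq_len(ncol(components))) {
    a <- components[, j] / sqrt(sum(components[, j]^2))
    b <- oracle_components[, j] / sqrt(sum(oracle_components[, j]^2))
    d <- min(max(abs(a - b)), max(abs(a + b)))
    testthat::expect_lt(d, tol)
  }
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# small random SPD-ish affinity for oracle tests
random_affinity <- function(n, seed) {
  set.seed(seed)
  X <- matrix(rnorm(n * 3), n, 3)
  A <- exp(-as.matrix(dist(X)))
  diag(A) <- 1
  A
}
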