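# Group-consensus connectivity builders and receptome coupling statistics.

check_stack <- function(stack) {
  if (!length(stack)) stop_invalid("empty subject stack")
  dims <- vapply(stack, function(m) dim(as.matrix(m)), integer(2))
  if (length(unique(dims[1, ])) != 1 || length(unique(dims[2, ])) != 1 ||
      dims[1, 1] != dims[2, 1]) {
    stop_invalid("all subject matrices must be square with equal size")
  }
  invisible(TRUE)
}

#' Group-consensus functional connectivity
#'
#' Subject matrices undergo Fisher's r-to-z transformation (`atanh`) and are
#' averaged entrywise. The consensus is kept on the z scale by default
#' (monotone-equivalent for all rank-based downstream steps); set
#' `back_transform = TRUE` for correlations. The diagonal is set to 0.
#'
#' @param stack list of square FC matrices with off-diagonal entries in
#'   `(-1, 1)`.
#' @param back_transform apply `tanh` to return to the correlation scale.
#' @return a [similarity_matrix()] of kind `"FC"`.
#' @export
consensus_fc <- function(stack, back_transform = FALSE) {
  check_stack(stack)
  zsum <- NULL
  for (s in seq_along(stack)) {
    m <- as.matrix(stack[[s]])
    off <- m[row(m) != col(m)]
    if (any(abs(off) >= 1)) {
      bad <- which(abs(m) >= 1 & row(m) != col(m), arr.ind = TRUE)[1, ]
      stop_invalid("subject %d has |r| >= 1 at entry (%d, %d)", s,
                   bad[1], bad[2])
    }
    diag(m) <- 0
    z <- atanh(m)
    zsum <- if (is.null(zsum)) z else zsum + z
  }
  out <- zsum / length(stack)
  if (back_transform) out <- tanh(out)
  diag(out) <- 0
  similarity_matrix((out + t(out)) / 2,
                    row_ids = rownames(as.matrix(stack[[1]])),
                    kind = "FC")
}

#' Group-consensus structural connectivity with distance-binned thresholding
#'
#' Subject matrices are `log(1 + w)`-transformed and averaged; the consensus
#' support is then chosen by distance-dependent consistency thresholding:
#' edges are grouped into `n_bins` equal-width length bins, each bin's
#' retention quota follows the pooled subject edge-length distribution
#' (largest-remainder allocation of the average subject edge count), and
#' within each bin the edges present in the most subjects are kept (ties by
#' higher mean weight). This corrects the over-representation of short and
#' under-representation of long connections that naive consensus averaging
#' produces.
#'
#' @param stack list of square nonnegative SC matrices.
#' @param dist symmetric region distance matrix.
#' @param n_bins number of edge-length bins (default 10).
#' @return a [similarity_matrix()] of kind `"SC"` (log scale, zero off the
#'   consensus support).
#' @export
consensus_sc <- function(stack, dist, n_bins = 10L) {
  check_stack(stack)
  n <- nrow(as.matrix(stack[[1]]))
  check_square_symmetric(dist, what = "distance matrix")
  if (nrow(dist) != n) stop_invalid("dist/stack size mismatch")
  L <- matrix(0, n, n)
  Cnt <- matrix(0L, n, n)
  for (m in stack) {
    m <- as.matrix(m)
    if (min(m) < 0) stop_invalid("SC weights must be nonnegative")
    L <- L + log1p(m)
    Cnt <- Cnt + (m > 0)
  }
  L <- L / length(stack)
  ut <- which(upper.tri(L))
  d_ut <- dist[ut]
  cnt_ut <- Cnt[ut]
  w_ut <- L[ut]
  # pooled subject edge-length distribution and total target count
  subj_edges <- vapply(stack, function(m) sum(as.matrix(m)[ut] > 0), 0L)
  target <- round(mean(subj_edges))
  brks <- seq(min(d_ut), max(d_ut), length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(d_ut, brks, rightmost.closed = TRUE), 1),
              n_bins)
  pooled <- vapply(seq_len(n_bins), function(b) {
    sum(cnt_ut[bin == b])
  }, 0)
  share <- if (sum(pooled) > 0) pooled / sum(pooled) else
    rep(1 / n_bins, n_bins)
  quota_raw <- target * share
  quota <- floor(quota_raw)
  rem <- target - sum(quota)
  if (rem > 0) {
    extra <- order(quota_raw - quota, decreasing = TRUE)[seq_len(rem)]
    quota[extra] <- quota[extra] + 1
  }
  keep <- logical(length(ut))
  for (b in seq_len(n_bins)) {
    idx <- which(bin == b & cnt_ut > 0)
    kq <- min(quota[b], length(idx))
    if (kq > 0) {
      o <- order(cnt_ut[idx], w_ut[idx], -idx, decreasing = TRUE)
      keep[idx[o[seq_len(kq)]]] <- TRUE
    }
  }
  out <- matrix(0, n, n)
  out[ut[keep]] <- w_ut[keep]
  out <- out + t(out)
  similarity_matrix(out, row_ids = rownames(as.matrix(stack[[1]])),
                    kind = "SC")
}

#' Microstructural profile covariance from depth-wise intensity profiles
#'
#' Each pair of region profiles is partially correlated controlling for the
#' grand-mean cortical intensity profile (residualize both on the mean
#' profile, then correlate the residuals). The partial correlations are then
#' mapped to a log scale: negatives are clipped to 0 and
#' `MPC = log((1 + r) / (1 - r))` (monotone on `[0, 1)`, zero-preserving);
#' rank-based downstream use makes log variants equivalent.
#'
#' @param profiles region-by-depth intensity matrix (>= 3 depth samples; the
#'   reference pipeline samples 14 equivolumetric surfaces).
#' @return a [similarity_matrix()] of kind `"MPC"` with zero diagonal.
#' @export
compute_mpc <- function(profiles) {
  profiles <- as.matrix(profiles)
  if (ncol(profiles) < 3) stop_invalid("need >= 3 depth samples per region")
  mean_prof <- colMeans(profiles)
  X <- cbind(1, mean_prof)
  resid <- t(profiles) - X %*% solve(crossprod(X), crossprod(X, t(profiles)))
  sds <- apply(resid, 2, stats::sd)
  if (any(sds < 1e-12)) {
    stop_invalid("degenerate region(s) (profile equals the mean profile): %s",
                 paste(utils::head(which(sds < 1e-12), 5), collapse = ", "))
  }
  r <- stats::cor(resid)
  r <- pmin(pmax(r, 0), 1 - 1e-6)
  mpc <- log((1 + r) / (1 - r))
  diag(mpc) <- 0
  mpc <- (mpc + t(mpc)) / 2
  similarity_matrix(mpc, row_ids = rownames(profiles), kind = "MPC")
}

#' Row-wise receptome coupling
#'
#' For each region, the Spearman correlation between the receptome row and
#' the corresponding row of another modality's matrix, over the indices where
#' both rows are nonzero (the diagonal excluded). Rows with fewer than 3
#' shared nonzero entries yield `NA` with a warning.
#'
#' @param receptome square [similarity_matrix()].
#' @param other square matrix over the same regions (may be sparse).
#' @return named numeric vector of per-region coupling values.
#' @export
row_coupling <- function(receptome, other) {
  A <- as.matrix(receptome)
  B <- as.matrix(other)
  if (!all(dim(A) == dim(B))) stop_invalid("matrices differ in size")
  n <- nrow(A)
  out <- rep(NA_real_, n)
  short <- integer(0)
  for (i in seq_len(n)) {
    j <- which(A[i, ] != 0 & B[i, ] != 0 & seq_len(n) != i)
    if (length(j) < 3) {
      short <- c(short, i)
    } else {
      out[i] <- spearman(A[i, j], B[i, j])
    }
  }
  if (length(short)) {
    warning("fewer than 3 shared nonzero entries for region(s): ",
            paste(utils::head(short, 5), collapse = ", "), call. = FALSE)
  }
  names(out) <- rownames(A)
  out
}

#' Kruskal-Wallis and Dunn's post hoc comparison across classes
#'
#' Tests whether per-region values (e.g. coupling strengths) differ across
#' cytoarchitectural classes: the tie-corrected Kruskal-Wallis `h` with its
#' chi-squared p-value, followed by pairwise Dunn tests (large-sample normal
#' approximation with tie correction) Bonferroni-adjusted over all class
#' pairs. Classes with fewer than 2 members are excluded with a warning.
#'
#' @param values per-region numeric values (NA dropped).
#' @param atlas per-region class labels (factor or character).
#' @return list with `h`, `p_global`, and `pairwise` (data.frame of Dunn `z`
#'   and adjusted p per class pair).
#' @export
class_comparison <- function(values, atlas) {
  grp <- as.character(atlas)
  ok <- is.finite(values)
  values <- values[ok]; grp <- grp[ok]
  sizes <- table(grp)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("excluding class(es) with < 2 members: ",
            paste(small, collapse = ", "), call. = FALSE)
    keep <- !(grp %in% small)
    values <- values[keep]; grp <- grp[keep]
  }
  classes <- sort(unique(grp))
  if (length(classes) < 2) stop_invalid("need >= 2 classes with >= 2 members")
  kw <- stats::kruskal.test(values, factor(grp))
  N <- length(values)
  rk <- rank(values)
  ties <- table(rk)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  mean_rank <- tapply(rk, grp, mean)
  n_g <- tapply(rk, grp, length)
  pairs <- utils::combn(classes, 2)
  z <- apply(pairs, 2, function(pr) {
    se <- sqrt((N * (N + 1) / 12 - tie_corr) *
                 (1 / n_g[[pr[1]]] + 1 / n_g[[pr[2]]]))
    (mean_rank[[pr[1]]] - mean_rank[[pr[2]]]) / se
  })
  p_adj <- stats::p.adjust(2 * stats::pnorm(-abs(z)), method = "bonferroni")
  list(h = unname(kw$statistic), p_global = kw$p.value,
       pairwise = data.frame(class_a = pairs[1, ], class_b = pairs[2, ],
                             z = z, p_adjusted = p_adj))
}
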