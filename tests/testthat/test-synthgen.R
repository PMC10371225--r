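test_that("sphere geometry satisfies its contracts", {
  g <- make_sphere_geometry(100, seed = 1)
  expect_equal(sqrt(rowSums(g$coords^2)), rep(1, 100), tolerance = 1e-9)
  expect_true(all(diag(g$dist) == 0))
  expect_equal(g$dist, t(g$dist))
  expect_setequal(unique(g$hemisphere), c("L", "R"))
  # triangle inequality on sampled triples
  set.seed(2)
  for (r in 1:200) {
    ijk <- sample.int(100, 3)
    expect_lte(g$dist[ijk[1], ijk[2]],
               g$dist[ijk[1], ijk[3]] + g$dist[ijk[3], ijk[2]] + 1e-12)
  }
  # antipodal pair has great-circle distance pi
  g2 <- geometry(rbind(c(0, 0, 1), c(0, 0, -1), c(1, 0, 0), c(0, 1, 0)),
                 acos(pmin(pmax(tcrossprod(rbind(c(0, 0, 1), c(0, 0, -1),
                                                 c(1, 0, 0), c(0, 1, 0))),
                                -1), 1)) * (1 - diag(4)),
                 hemisphere = c("R", "R", "R", "R"))
  expect_equal(g2$dist[1, 2], pi)
  # determinism and seed sensitivity
  expect_identical(make_sphere_geometry(50, seed = 7)$coords,
                   make_sphere_geometry(50, seed = 7)$coords)
  expect_false(identical(make_sphere_geometry(50, seed = 7)$coords,
                         make_sphere_geometry(50, seed = 8)$coords))
  expect_error(make_sphere_geometry(3), "n_nodes")
  # medial fraction marks nodes nearest the midline
  gm <- make_sphere_geometry(100, seed = 1, medial_frac = 0.1)
  expect_equal(sum(gm$medial_mask), 10)
})

test_that("autocorrelated maps interpolate between i.i.d. and constant", {
  g <- make_sphere_geometry(100, seed = 1)
  # tiny length scale: nearest-neighbour correlation near zero
  x0 <- simulate_autocorrelated_map(g, 1e-4, seed = 2)
  nn <- apply(g$dist + diag(99, 100), 1, which.min)
  expect_lt(abs(cor(x0, x0[nn])), 0.25)
  # huge length scale: map variance collapses relative to field variance 1
  xl <- simulate_autocorrelated_map(g, 500, seed = 2)
  expect_lt(var(xl), 0.05)
  # determinism
  expect_identical(simulate_autocorrelated_map(g, 0.5, seed = 3),
                   simulate_autocorrelated_map(g, 0.5, seed = 3))
  expect_error(simulate_autocorrelated_map(g, 0), "length_scale")
})

test_that("autocorrelated maps have distance-increasing semivariance", {
  g <- make_sphere_geometry(100, seed = 1)
  x <- simulate_autocorrelated_map(g, 0.5, seed = 3)
  v <- empirical_variogram(x, g$dist, 10)
  # rising over the well-populated short-range bins
  expect_true(all(diff(v$gamma[2:4]) >= 0))
  # short-range vs long-range semivariance, per draw, over 100 seeds
  ut <- upper.tri(g$dist)
  pd <- g$dist[ut]
  ii <- row(g$dist)[ut]; jj <- col(g$dist)[ut]
  ratio <- function(vals) {
    sq <- 0.5 * (vals[ii] - vals[jj])^2
    mean(sq[pd < 0.5]) / mean(sq[pd > 1.5])
  }
  r_ac <- vapply(1:100, function(s) {
    ratio(simulate_autocorrelated_map(g, 0.5, seed = s))
  }, 0)
  expect_gte(mean(r_ac < 0.9), 0.95)
  # white noise shows no such decay (contrast)
  set.seed(1)
  r_wn <- vapply(1:50, function(s) ratio(rnorm(100)), 0)
  expect_gt(median(r_wn), median(r_ac) + 0.2)
})

test_that("density panels carry planted axes and honour the noise contract", {
  g <- make_sphere_geometry(80, seed = 4)
  sim <- simulate_density_panel(g, n_molecules = 19, n_axes = 3,
                                noise_sd = 0.1, seed = 5)
  expect_equal(dim(sim$panel$values), c(80, 19))
  expect_equal(sim$panel$molecules[1], "5-HTT")
  # planted axes mutually orthogonal after centring
  ax <- sim$truth$planted_axes
  g_mat <- crossprod(scale(ax, scale = FALSE))
  expect_lt(max(abs(g_mat[upper.tri(g_mat)])), 1e-8)
  # noiseless single axis: every molecule is perfectly rank-correlated
  s0 <- simulate_density_panel(g, n_molecules = 6, n_axes = 1, noise_sd = 0,
                               seed = 6)
  rho <- apply(s0$panel$values, 2, cor, y = s0$truth$planted_axes[, 1],
               method = "spearman")
  expect_equal(unname(abs(rho)), rep(1, 6))
  # bitwise determinism
  expect_identical(simulate_density_panel(g, 19, 3, seed = 9)$panel$values,
                   simulate_density_panel(g, 19, 3, seed = 9)$panel$values)
  expect_error(simulate_density_panel(g, 19, 3, noise_sd = -1), "noise_sd")
  expect_error(simulate_density_panel(g, 2, 3), "n_molecules")
})

test_that("signed block matrices plant recoverable community structure", {
  noiseless <- simulate_signed_blocks(10, 2, w_in = 0.8, w_out = -0.4,
                                      noise_sd = 0, seed = 1)
  m <- as.matrix(noiseless$matrix)
  off <- m[upper.tri(m)]
  expect_setequal(unique(off), c(0.8, -0.4))
  one <- simulate_signed_blocks(8, 1, noise_sd = 0, seed = 1)
  expect_true(all(as.matrix(one$matrix)[upper.tri(one$matrix)] == 0.8))
  expect_error(simulate_signed_blocks(5, 6), "n_blocks")
  expect_error(simulate_signed_blocks(10, 2, w_in = -1, w_out = -2), "w_in")
  # planted partition maximizes the signed quality on a 9-node subsample,
  # verified by exhaustive enumeration over all 21147 partitions
  sb <- simulate_signed_blocks(60, 3, w_in = 0.8, w_out = -0.4,
                               noise_sd = 0.05, seed = 11)
  sub <- c(1:3, 21:23, 41:43)
  W <- as.matrix(sb$matrix)[sub, sub]
  diag(W) <- 0
  Wp <- pmax(W, 0); Wn <- pmax(-W, 0)
  vp <- sum(Wp); vn <- sum(Wn)
  kp <- rowSums(Wp); kn <- rowSums(Wn)
  qfun <- function(lab) {
    same <- outer(lab, lab, "==")
    (sum(Wp * same) - sum(outer(kp, kp) * same) / vp) / vp -
      (vn / (vp + vn)) *
        ((sum(Wn * same) - sum(outer(kn, kn) * same) / vn) / vn)
  }
  parts <- enum_partitions(9)
  qs <- apply(parts, 1, qfun)
  best <- parts[which.max(qs), ]
  expect_equal(ari(best, sb$truth$planted_partition[sub]), 1)
})

test_that("subject stacks have the advertised per-kind structure", {
  g <- make_sphere_geometry(60, seed = 3)
  fc <- simulate_subject_stack(g, 4, "FC", seed = 1)
  expect_length(fc, 4)
  for (m in fc) {
    expect_true(all(as.matrix(m) >= -1 & as.matrix(m) <= 1))
    expect_true(isSymmetric(unclass(m)))
  }
  # single-subject FC consensus is that subject's matrix after atanh
  cons1 <- consensus_fc(fc[1])
  expected <- as.matrix(fc[[1]]); diag(expected) <- 0
  expect_equal(unclass(cons1), atanh(expected), ignore_attr = TRUE,
               tolerance = 1e-12)
  sc <- simulate_subject_stack(g, 8, "SC", seed = 2)
  expect_true(all(vapply(sc, function(m) min(m) >= 0, TRUE)))
  # naive strongest-edge consensus over-represents short edges relative to
  # the distance-binned consensus
  cs <- consensus_sc(sc, g$dist, n_bins = 8)
  ut <- upper.tri(g$dist)
  L <- Reduce(`+`, lapply(sc, function(m) log1p(as.matrix(m)))) / length(sc)
  ne <- sum(as.matrix(cs)[ut] != 0)
  naive <- order(L[ut], decreasing = TRUE)[seq_len(ne)]
  expect_lt(mean(g$dist[ut][naive]), mean(g$dist[ut][as.matrix(cs)[ut] != 0]))
  expect_error(simulate_subject_stack(g, 0, "FC"), "n_subjects")
})

test_that("coupled-modality fixtures plant class-ordered row coupling", {
  g <- make_sphere_geometry(80, seed = 5)
  cls <- rep(c("idiotypic", "heteromodal"), each = 40)
  cm <- simulate_coupled_modalities(g, cls,
                                    c(idiotypic = 0.8, heteromodal = 0.3),
                                    seed = 2)
  cv <- row_coupling(cm$reference, cm$other)
  expect_gt(mean(cv[cls == "idiotypic"]), mean(cv[cls == "heteromodal"]))
  expect_error(simulate_coupled_modalities(g, cls, c(idiotypic = 0.8)),
               "every class")
})
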