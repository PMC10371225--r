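test_that("signed quality matches hand values and brute-force edge sums", {
  # all-positive uniform matrix, single community, gamma = 1: Q* = 0
  u <- matrix(0.5, 6, 6); diag(u) <- 1
  expect_equal(signed_quality(similarity_matrix(u, kind = "affinity"),
                              rep(0, 6), gamma = 1), 0, tolerance = 1e-12)
  # planted 2-block signed toy: planted beats the single community
  toy <- rbind(c(1, 1, -1, -1), c(1, 1, -1, -1),
               c(-1, -1, 1, 1), c(-1, -1, 1, 1))
  sm <- similarity_matrix(toy, kind = "receptome")
  q_planted <- signed_quality(sm, c(0, 0, 1, 1))
  q_single <- signed_quality(sm, rep(0, 4))
  expect_gt(q_planted, q_single)
  # brute-force equality on random signed 15-node matrices
  for (seed in 1:5) {
    set.seed(seed)
    E <- matrix(rnorm(225), 15, 15)
    W <- (E + t(E)) / 2
    diag(W) <- 1
    labels <- sample(0:3, 15, replace = TRUE)
    gamma <- runif(1, 0.5, 2)
    expect_equal(signed_quality(similarity_matrix(pmin(pmax(W, -1), 1),
                                                  kind = "receptome"),
                                labels, gamma),
                 brute_signed_quality(pmin(pmax(W, -1), 1), labels, gamma),
                 tolerance = 1e-12)
  }
  expect_error(signed_quality(similarity_matrix(diag(4), kind = "affinity"),
                              rep(0, 4)), "weight")
})

test_that("leiden recovers planted blocks and attains the exhaustive optimum", {
  sb <- simulate_signed_blocks(45, 3, w_in = 0.8, w_out = -0.4,
                               noise_sd = 0.05, seed = 2)
  p <- leiden_partition(sb$matrix, gamma = 1, seed = 3)
  expect_equal(ari(p$labels, sb$truth$planted_partition), 1)
  # labels are contiguous from 0
  expect_setequal(unique(p$labels), 0:(p$n_communities - 1))
  # determinism under a fixed seed
  p2 <- leiden_partition(sb$matrix, gamma = 1, seed = 3)
  expect_identical(p$labels, p2$labels)
  # all-positive uniform graph collapses to one community at small gamma
  u <- matrix(0.6, 10, 10); diag(u) <- 1
  p1 <- leiden_partition(similarity_matrix(u, kind = "affinity"),
                         gamma = 1e-6, seed = 1)
  expect_equal(p1$n_communities, 1)
  # 8-node toy: achieved quality equals the exhaustive maximum over all
  # 4140 partitions
  sb8 <- simulate_signed_blocks(8, 2, w_in = 0.9, w_out = -0.5,
                                noise_sd = 0.1, seed = 4)
  parts <- enum_partitions(8)
  qs <- apply(parts, 1, function(lab) {
    brute_signed_quality(as.matrix(sb8$matrix), lab, 1)
  })
  found <- leiden_partition(sb8$matrix, gamma = 1, seed = 5)
  expect_equal(found$quality, max(qs), tolerance = 1e-10)
})

test_that("z-rand matches exhaustive pair counting and calibrates to zero", {
  # exhaustive pair-count oracle on 8-node partitions
  set.seed(6)
  for (r in 1:5) {
    lp <- sample(0:2, 8, replace = TRUE)
    lq <- sample(0:2, 8, replace = TRUE)
    br <- brute_zrand(lp, lq)
    # rebuild the z score from the brute-force counts with the published
    # hypergeometric moments and compare with the implementation
    n <- 8; M <- n * (n - 1) / 2
    n1 <- table(lp); n2 <- table(lq)
    C1 <- n * (n^2 - 3 * n - 2) - 8 * (n + 1) * br$M1 + 4 * sum(n1^3)
    C2 <- n * (n^2 - 3 * n - 2) - 8 * (n + 1) * br$M2 + 4 * sum(n2^3)
    a <- 4 * br$M1 - 2 * M; b <- 4 * br$M2 - 2 * M
    varw <- M / 16 - (a^2 * b^2) / (256 * M^2) +
      C1 * C2 / (16 * n * (n - 1) * (n - 2)) +
      (a^2 - 4 * C1 - 4 * M) * (b^2 - 4 * C2 - 4 * M) /
        (64 * n * (n - 1) * (n - 2) * (n - 3))
    if (varw > 0) {
      expect_equal(zrand(lp, lq), (br$w - br$mu) / sqrt(varw),
                   tolerance = 1e-12)
    }
    expect_equal(zrand(lp, lq), zrand(lq, lp))
  }
  # independent uniform partitions have mean z-rand near 0
  set.seed(7)
  zs <- replicate(1000, zrand(sample(0:3, 40, replace = TRUE),
                              sample(0:3, 40, replace = TRUE)))
  expect_lt(abs(mean(zs)), 0.1)
  # self-similarity of a non-trivial partition is positive
  expect_gt(zrand(rep(0:4, each = 8), rep(0:4, each = 8)), 0)
  expect_error(zrand(0:4, 0:3), "length")
})

test_that("default resolution grids have the documented sizes", {
  expect_length(gamma_grid_cortical(), 191)
  expect_length(gamma_grid_subcortical(), 19)
  expect_equal(range(gamma_grid_cortical()), c(0.5, 10))
  expect_equal(range(gamma_grid_subcortical()), c(1, 10))
})

test_that("ensembles pick the max-mean-z-rand consensus on planted blocks", {
  sb <- simulate_signed_blocks(36, 3, w_in = 0.8, w_out = -0.4,
                               noise_sd = 0.05, seed = 8)
  ens <- partition_ensemble(sb$matrix, gamma_grid = c(0.8, 1, 1.2),
                            n_reps = 8, seed = 9)
  for (pg in ens$per_gamma) {
    expect_equal(pg$mean_zrand[pg$consensus_index], max(pg$mean_zrand))
    # planted structure: all runs identical, z-rand variance 0
    expect_equal(pg$zrand_variance, 0, tolerance = 1e-12)
    expect_equal(ari(pg$consensus$labels, sb$truth$planted_partition), 1)
  }
  expect_error(partition_ensemble(sb$matrix, numeric(0), 5), "gamma")
  expect_error(partition_ensemble(sb$matrix, 1, n_reps = 1), "n_reps")
})

test_that("modular stability follows its closed form", {
  # Cmax = 1, Cin = 1, Ctot = 4, s = 0.25 -> 0.1875
  p <- partition(c(rep(0, 5), rep(1, 5), rep(2, 5), rep(3, 5)), gamma = 1)
  ms <- modular_stability(list(p), roi_mask = 1:5)
  expect_equal(ms$score, 0.1875)
  expect_equal(ms$cmax, 1)
  # ROI fragmented into all communities scores 0
  frag <- modular_stability(list(p), roi_mask = c(1, 6, 11, 16))
  expect_equal(frag$score, 0)
  # nested ROI beats an evenly split ROI of the same size
  p8 <- partition(rep(0:7, each = 4), gamma = 2)
  nested <- modular_stability(list(p8), roi_mask = 1:4)$score
  split2 <- modular_stability(list(p8), roi_mask = c(1, 2, 5, 6))$score
  expect_gt(nested, split2)
  # invariant to community relabelling
  relab <- partition((p$labels + 2) %% 4, gamma = 1)
  expect_equal(modular_stability(list(relab), 1:5)$score, 0.1875)
  # divide-by-s variant exposed
  expect_equal(modular_stability(list(p), 1:5,
                                 normalization = "divide")$score,
               0.1875 / 0.25^2)
  expect_error(modular_stability(list(p), integer(0)), "empty ROI")
})

test_that("WPGMA clustering reproduces the hand recursion", {
  # two leaves at distance 3 merge at height 3
  two <- wpgma_cluster(matrix(c(0, 3), 2, 1,
                              dimnames = list(c("a", "b"), NULL)))
  expect_equal(two$height, 3)
  # 4 points on a line at 0, 1, 10, 11
  hc <- wpgma_cluster(matrix(c(0, 1, 10, 11), 4, 1,
                             dimnames = list(letters[1:4], NULL)))
  expect_equal(hc$height, c(1, 1, 10))
  expect_equal(sort(unlist(cutree(hc, 2))), sort(c(a = 1, b = 1, c = 2,
                                                   d = 2)))
  # mirrored hemispheres with tiny noise merge with their counterparts first
  set.seed(10)
  base <- matrix(rnorm(4 * 6), 4, 6)
  feats <- rbind(base, base + matrix(rnorm(24, sd = 0.01), 4, 6))
  rownames(feats) <- c(paste0("L_", 1:4), paste0("R_", 1:4))
  hm <- wpgma_cluster(feats)
  first_merges <- hm$merge[1:4, ]
  for (r in 1:4) {
    pair <- sort(abs(first_merges[r, ]))
    expect_equal(hm$labels[pair[2]],
                 sub("^L", "R", hm$labels[pair[1]]))
  }
  expect_error(wpgma_cluster(matrix(0, 1, 3)), "2 rows")
  dup <- matrix(0:5, 2, 3)
  rownames(dup) <- c("x", "x")
  expect_error(wpgma_cluster(dup), "duplicate")
})
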