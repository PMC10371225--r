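test_that("row thresholding keeps the top of each row and zeroes the rest", {
  m <- matrix(c(1, .9, .5, .1,
                .9, 1, .05, .5,
                .5, .05, 1, .9,
                .1, .5, .9, 1), 4, 4, byrow = TRUE)
  sm <- similarity_matrix(m, kind = "receptome")
  th75 <- as.matrix(threshold_rows(sm, 75))
  expect_equal(th75[1, ], c(0, .9, 0, 0), ignore_attr = TRUE)
  # pct = 0 keeps all off-diagonal entries
  th0 <- as.matrix(threshold_rows(sm, 0))
  expect_equal(th0[1, -1], m[1, -1], ignore_attr = TRUE)
  expect_true(all(diag(th0) == 0))
  # each row of a tie-free 20x20 retains exactly ceiling(10%) entries
  set.seed(3)
  E <- matrix(runif(400), 20, 20)
  E <- (E + t(E)) / 2
  diag(E) <- 1
  th90 <- as.matrix(threshold_rows(similarity_matrix(E, kind = "affinity"),
                                   90))
  expect_equal(unname(rowSums(th90 != 0)), rep(ceiling(0.1 * 19), 20))
  expect_error(threshold_rows(sm, 100), "pct")
})

test_that("normalized-angle affinity hits its closed-form anchor values", {
  rows <- rbind(c(1, 0), c(2, 0), c(0, 3), c(-1, 0))
  aff <- normalized_angle_affinity(similarity_matrix(rows, kind = "cross",
                                                     symmetric = FALSE))
  expect_equal(aff[1, 2], 1)       # parallel
  expect_equal(aff[1, 3], 0.5)     # orthogonal
  expect_equal(aff[1, 4], 0)       # anti-parallel
  expect_true(all(as.matrix(aff) >= 0 & as.matrix(aff) <= 1))
  expect_error(normalized_angle_affinity(
    similarity_matrix(rbind(c(0, 0), c(1, 1)), kind = "cross",
                      symmetric = FALSE)), "zero-norm")
})

test_that("diffusion embedding matches a dense eigensolver oracle", {
  for (seed in 1:20) {
    n <- sample(12:30, 1)
    W <- random_affinity(n, seed)
    gs <- diffusion_embedding(similarity_matrix(W, kind = "affinity"),
                              alpha = 0.5, n_components = 5)
    or <- oracle_diffusion(W, alpha = 0.5, k = 5)
    expect_equal(gs$eigenvalues, or$values, tolerance = 1e-8)
    expect_embedding_match(gs$components, or$components, tol = 1e-8)
  }
})

test_that("embedding is equivariant under node permutation", {
  W <- random_affinity(15, 42)
  gs <- diffusion_embedding(similarity_matrix(W, kind = "affinity"),
                            n_components = 3)
  set.seed(1)
  perm <- sample(15)
  gsp <- diffusion_embedding(similarity_matrix(W[perm, perm],
                                               kind = "affinity"),
                             n_components = 3)
  for (j in 1:3) {
    d <- min(max(abs(gsp$components[, j] - gs$components[perm, j])),
             max(abs(gsp$components[, j] + gs$components[perm, j])))
    expect_lt(d, 1e-9)
  }
  expect_equal(gsp$eigenvalues, gs$eigenvalues, tolerance = 1e-10)
})

test_that("the leading gradient separates two weakly-connected blocks", {
  n <- 12
  W <- matrix(1e-3, n, n)
  W[1:6, 1:6] <- 1
  W[7:12, 7:12] <- 1
  gs <- diffusion_embedding(similarity_matrix(W, kind = "affinity"),
                            n_components = 2)
  g1 <- gs$components[, 1]
  expect_true(all(sign(g1[1:6]) == sign(g1[1])))
  expect_true(all(sign(g1[7:12]) == -sign(g1[1])))
  # variance fractions sum to one and eigenvalues are sorted
  expect_equal(sum(gs$variance_fraction), 1, tolerance = 1e-9)
  expect_true(all(diff(gs$eigenvalues) <= 1e-12))
  # a disconnected affinity is rejected
  W0 <- W; W0[1:6, 7:12] <- 0; W0[7:12, 1:6] <- 0
  expect_error(diffusion_embedding(similarity_matrix(W0, kind = "affinity")),
               "disconnected")
})

test_that("procrustes alignment recovers rotations and reflections", {
  W <- random_affinity(20, 3)
  ref <- diffusion_embedding(similarity_matrix(W, kind = "affinity"),
                             n_components = 4)
  expect_equal(align_procrustes(ref, ref)$components, ref$components,
               tolerance = 1e-12)
  flipped <- ref
  flipped$components <- -ref$components
  expect_equal(align_procrustes(ref, flipped)$components, ref$components,
               tolerance = 1e-12)
  set.seed(8)
  Q <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  rotated <- ref
  rotated$components <- ref$components %*% Q
  expect_equal(align_procrustes(ref, rotated)$components, ref$components,
               tolerance = 1e-9)
  bad <- ref
  bad$components <- ref$components[, 1:2]
  expect_error(align_procrustes(ref, bad), "component")
})

test_that("rectangular embedding is consistent with the square case", {
  g <- make_sphere_geometry(30, seed = 9)
  panel <- zscore_panel(simulate_density_panel(g, 8, 2, seed = 9)$panel,
                        "joint")
  rc <- build_receptome(panel)
  sq <- compute_gradients(rc, n_components = 3)
  cross <- similarity_matrix(as.matrix(rc), kind = "cross", symmetric = FALSE)
  # some columns may receive no positive suprathreshold weight; the column
  # projection warns and leaves those NA
  re <- suppressWarnings(embed_rectangular(cross, n_components = 3))
  expect_equal(re$rows$components, sq$components, tolerance = 1e-10)
  # duplicated rows receive identical gradient values
  m2 <- as.matrix(rc)[c(1, 1:29), ]
  rownames(m2) <- sprintf("r%02d", 1:30)
  re2 <- embed_rectangular(similarity_matrix(m2, kind = "cross",
                                             symmetric = FALSE),
                           n_components = 2)
  expect_equal(re2$rows$components[1, ], re2$rows$components[2, ],
               tolerance = 1e-8)
  # toy 6 x 8 cross-matrix: row embedding matches the dense oracle applied
  # to the same thresholded-row affinity
  set.seed(11)
  toy <- matrix(rnorm(48), 6, 8)
  te <- embed_rectangular(similarity_matrix(toy, kind = "cross",
                                            symmetric = FALSE),
                          n_components = 3, threshold_pct = 50)
  aff <- as.matrix(normalized_angle_affinity(
    threshold_rows(similarity_matrix(toy, kind = "cross",
                                     symmetric = FALSE), 50)))
  or <- oracle_diffusion(aff, alpha = 0.5, k = 3)
  expect_embedding_match(te$rows$components, or$components, tol = 1e-8)
  expect_equal(dim(te$cols), c(8, 3))
})

test_that("variance-fraction significance flags planted structure only", {
  g <- make_sphere_geometry(40, seed = 10)
  strong <- simulate_density_panel(g, 10, 1, noise_sd = 0.05, seed = 10)
  res <- component_significance(strong$panel, g, n_null = 19, seed = 2,
                                n_components = 5)
  expect_equal(res$p[1], 1 / 20, tolerance = 1e-12)
  # a structureless i.i.d. panel is not flagged (frozen seed)
  set.seed(5)
  noise_panel <- density_panel(matrix(rnorm(40 * 10), 40, 10))
  res0 <- component_significance(noise_panel, g, n_null = 19, seed = 3,
                                 n_components = 5)
  expect_gt(res0$p[1], 0.1)
  expect_error(component_significance(strong$panel, g, n_null = 0), "n_null")
})
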