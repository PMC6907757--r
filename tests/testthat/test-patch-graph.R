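test_that("patch features have one row per pixel and the documented layout", {
  img <- image_grid(matrix(runif_det(25), 5, 5))
  ft <- extract_patch_features(img, patch_config(s = 3, k = 2,
                                                 lambda_spatial = 0.05))
  expect_identical(dim(ft$features), c(25L, 11L))
  # center pixel of the patch equals the image value (row-major node 7
  # is image position (2, 2); patch center sits at column 5 for s = 3)
  expect_identical(ft$features[7, 5], unclass(img)[2, 2])
  # coordinate columns carry lambda-scaled 0-based indices
  expect_identical(ft$features[7, 10], 0.05 * 1)
  expect_identical(ft$features[7, 11], 0.05 * 1)
})

test_that("lambda = 0 zeroes the coordinate columns; constant images give identical rows", {
  img <- image_grid(matrix(runif_det(64), 8, 8))
  ft <- extract_patch_features(img, patch_config(s = 3, lambda_spatial = 0))
  expect_true(all(ft$features[, 10:11] == 0))

  flat <- image_grid(matrix(0.3, 8, 8))
  ftc <- extract_patch_features(flat, patch_config(s = 3, lambda_spatial = 0))
  expect_true(all(apply(ftc$features, 2, function(col) all(col == col[1]))))
})

test_that("patch extraction rejects even or oversized patch sides", {
  img <- image_grid(matrix(0.5, 8, 8))
  expect_error(patch_config(s = 4), "odd")
  expect_error(extract_patch_features(img, patch_config(s = 9)),
               "exceeds")
})

test_that("knn edges match hand-computed neighbours on a 1-D example", {
  # features at positions 0, 1, 3: nearest of 0 is 1, of 1 is 0 (tie
  # broken by index against distance-2 node 3), of 3 is 1
  X <- matrix(c(0, 1, 3), ncol = 1)
  e <- knn_edges(X, 1)
  expect_identical(e$to, c(2L, 1L, 2L))
  expect_identical(e$dist, c(1, 1, 2))
})

test_that("every node gets exactly k out-edges, none to itself", {
  X <- matrix(runif_det(60), 20, 3)
  e <- knn_edges(X, 4)
  expect_identical(nrow(e), 80L)
  expect_true(all(e$from != e$to))
  expect_true(all(table(e$from) == 4L))
})

test_that("both exact backends agree with a full pairwise-distance sort", {
  for (seed in 1:3) {
    set.seed(seed)
    X <- matrix(rnorm(30 * 4), 30, 4)
    eb <- knn_edges(X, 4, backend = "brute")
    ek <- knn_edges(X, 4, backend = "kdtree")
    expect_identical(eb, ek)
    # O(n^2) oracle: sort all pairwise distances per node
    D <- as.matrix(stats::dist(X))
    diag(D) <- Inf
    for (i in 1:30) {
      oracle <- order(D[i, ], seq_len(30))[1:4]
      expect_equal(eb$to[eb$from == i], oracle)
    }
  }
})

test_that("knn rejects k >= n", {
  X <- matrix(runif_det(10), 5, 2)
  expect_error(knn_edges(X, 5), "smaller")
})

test_that("Gaussian kernel weights follow exp(-d^2/sigma^2) and symmetrize by union", {
  e <- data.frame(from = c(1L, 2L, 3L), to = c(2L, 1L, 1L),
                  dist = c(0, 0, 0.5))
  g <- build_weighted_graph(e, sigma_kernel = 0.5, n = 3)
  expect_identical(g$W[1, 2], 1)           # d = 0 -> w = 1
  expect_equal(g$W[1, 3], exp(-1))         # d = sigma -> w = e^-1
  expect_identical(as.matrix(g$W), t(as.matrix(g$W)))
  expect_true(all(Matrix::diag(g$W) == 0))
  expect_error(build_weighted_graph(e, sigma_kernel = 0), "positive")
})

test_that("kernel bandwidth follows the noise-variance rule with a noise-free fallback", {
  pc5 <- patch_config(s = 5)
  expect_equal(auto_kernel_bandwidth(noise_model(25.5, seed = 1), pc5),
               sqrt(0.05), tolerance = 1e-12)
  expect_identical(auto_kernel_bandwidth(noise_model(0, seed = 1), pc5), 0.1)
  # sigma scales linearly in the patch side
  s1 <- auto_kernel_bandwidth(noise_model(20, seed = 1), patch_config(s = 5))
  s2 <- auto_kernel_bandwidth(noise_model(20, seed = 1), patch_config(s = 9))
  expect_equal(s2 / s1, 9 / 5, tolerance = 1e-12)
})

test_that("grid graphs have the lattice edge counts and unit weights", {
  g22 <- grid_graph(2, 2, 4)
  expect_identical(nrow(g22$edges), 4L)
  g33 <- grid_graph(3, 3, 4)
  expect_identical(nrow(g33$edges), 12L)  # 2*m*l - m - l
  expect_true(all(g33$edges$w == 1))
  g338 <- grid_graph(3, 3, 8)
  expect_identical(nrow(g338$edges), 20L)  # + 2*(m-1)*(l-1) diagonals
  expect_identical(as.matrix(g33$W), t(as.matrix(g33$W)))
})

test_that("graph construction is permutation-consistent", {
  set.seed(14)
  X <- matrix(rnorm(18 * 5), 18, 5)
  perm <- sample.int(18)
  g1 <- build_weighted_graph(knn_edges(X, 3), 1.0, n = 18)
  g2 <- build_weighted_graph(knn_edges(X[perm, , drop = FALSE], 3), 1.0,
                             n = 18)
  # W2[a, b] must equal W1[perm[a], perm[b]]
  W1 <- as.matrix(g1$W)
  W2 <- as.matrix(g2$W)
  expect_equal(W2, W1[perm, perm], ignore_attr = TRUE)
})

test_that("a large spatial constraint drives neighbours to the spatially closest pixels", {
  img <- image_grid(matrix(runif_det(256), 16, 16))
  ft <- extract_patch_features(img, patch_config(s = 3, lambda_spatial = 1e3))
  e <- knn_edges(ft, 4)
  coords <- cbind(rep(0:15, each = 16), rep(0:15, times = 16))
  for (i in c(1, 18, 120, 256)) {
    d2 <- (coords[, 1] - coords[i, 1])^2 + (coords[, 2] - coords[i, 2])^2
    d2[i] <- Inf
    kth <- sort(d2)[4]
    picked <- e$to[e$from == i]
    # every selected neighbour lies within the spatial tie-closure of
    # the 4th-nearest coordinate distance
    expect_true(all(d2[picked] <= kth + 1e-9))
  }
})

test_that("node degrees are at least k after union symmetrization", {
  img <- image_grid(matrix(runif_det(144), 12, 12))
  ft <- extract_patch_features(img, patch_config(s = 3, k = 5))
  g <- build_weighted_graph(knn_edges(ft, 5), 0.5, n = 144)
  deg <- Matrix::rowSums(g$W != 0)
  expect_true(all(deg >= 5))
  expect_true(all(g$edges$w > 0 & g$edges$w <= 1))
})

test_that("edge lists round-trip through the text format", {
  g <- grid_graph(3, 4, 4)
  path <- tempfile(fileext = ".txt")
  on.exit(unlink(path))
  write_edge_list(g, path)
  g2 <- read_edge_list(path)
  expect_identical(g2$n, g$n)
  expect_equal(g2$edges, g$edges)
})
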