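test_that("patch extraction handles interior, degenerate, and mirrored borders", {
  const <- us_image(matrix(5, 5, 5))
  expect_equal(extract_patch(const, c(3, 3), 1), rep(5, 9))

  one <- us_image(matrix(3, 1, 1))
  expect_equal(extract_patch(one, c(1, 1), 0), 3)

  m <- matrix(1:9, 3, 3)  # distinct values
  # hand-built mirror pad of the corner (1,1): reflect row 2 above, col 2 left
  padded <- rbind(c(m[2, 2], m[2, 1], m[2, 2]),
                  c(m[1, 2], m[1, 1], m[1, 2]),
                  c(m[2, 2], m[2, 1], m[2, 2]))
  expect_equal(extract_patch(us_image(m), c(1, 1), 1), as.vector(padded))

  expect_error(extract_patch(const, c(0, 3), 1), "outside")
})

test_that("patch distance matches its formula and is a scale-equivariant divergence", {
  expect_equal(pearson_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  # hand evaluation: (4-2)^2 / ((4+2)/2) = 4/3
  expect_equal(pearson_distance(4, 2, eps = 1e-300), 4 / 3)

  set.seed(42)
  for (i in 1:20) {
    p <- runif(9, 0.1, 10); q <- runif(9, 0.1, 10); a <- runif(1, 0.1, 5)
    d <- pearson_distance(p, q, eps = 1e-300)
    expect_gte(d, 0)
    expect_equal(pearson_distance(q, p, eps = 1e-300), d)
    expect_equal(pearson_distance(a * p, a * q, eps = 1e-300), a * d,
                 tolerance = 1e-12)
  }
  expect_error(pearson_distance(1:3, 1:2), "mismatch")
  expect_error(pearson_distance(c(-1, 2), c(1, 2)), "nonnegative")
})

test_that("asymmetric distance variant uses the q denominator", {
  expect_equal(pearson_distance(4, 2, eps = 1e-300, symmetric = FALSE), 2)
})

test_that("graph weights are kernel values in (0,1], symmetric, and ordered by contrast", {
  const <- us_image(matrix(7, 8, 8))
  g <- build_graph(const, graph_config(window_radius = 2))
  expect_true(all(g$weights@x == 1))

  # two flat regions: cross-boundary weights below same-region weights
  img <- us_image(cbind(matrix(10, 8, 4), matrix(100, 8, 4)))
  g2 <- build_graph(img, graph_config(patch_radius = 1, window_radius = 2, sigma = 3))
  W <- as.matrix(g2$weights)
  left <- which(rep(1:8, each = 8) <= 3)   # column-major, away from boundary
  right <- which(rep(1:8, each = 8) >= 6)
  cross <- W[rep(1:8, each = 8) == 4, rep(1:8, each = 8) == 5]
  within <- c(W[left, left][W[left, left] > 0], W[right, right][W[right, right] > 0])
  expect_lt(max(cross), min(within))

  set.seed(3)
  noisy <- us_image(matrix(runif(100, 10, 200), 10, 10))
  g3 <- build_graph(noisy, graph_config(window_radius = 3))
  expect_equal(max(abs(g3$weights - Matrix::t(g3$weights))), 0)
  expect_true(all(g3$weights@x > 0 & g3$weights@x <= 1))
  expect_equal(Matrix::diag(g3$weights), rep(1, 100))

  # larger sigma never decreases a weight
  g4 <- build_graph(noisy, graph_config(window_radius = 3, sigma = 6))
  expect_true(all(g4$weights@x >= g3$weights@x - 1e-14))

  # window larger than the image is clipped, not an error
  tiny <- build_graph(us_image(matrix(1:12 + 0, 3, 4)),
                      graph_config(window_radius = 10))
  expect_equal(tiny$n_nodes, 12)
  expect_equal(length(tiny$weights@x), 12 * 12)  # complete graph + diagonal
})

test_that("graph Laplacian has zero row sums and is positive semidefinite", {
  set.seed(11)
  img <- us_image(matrix(runif(196, 0, 255), 14, 14))
  g <- build_graph(img, graph_config(window_radius = 3))
  expect_lt(max(abs(Matrix::rowSums(g$laplacian))), 1e-10)
  for (i in 1:50) {
    x <- rnorm(g$n_nodes)
    expect_gte(graph_quadratic(g, x), -1e-10)
  }
  ev <- min(eigen(as.matrix(g$laplacian), symmetric = TRUE,
                  only.values = TRUE)$values)
  expect_gte(ev, -1e-8)
})

test_that("cut weight equals the Laplacian quadratic form on binary indicators", {
  # 3-node path graph with unit weights: cutting off one end costs 1
  W <- matrix(0, 3, 3); W[1, 2] <- W[2, 1] <- 1; W[2, 3] <- W[3, 2] <- 1
  diag(W) <- 1
  gp <- make_test_graph(W, c(1, 3))
  expect_equal(cut_value(gp, c(1, 0, 0)), 1)
  expect_equal(cut_value(gp, c(1, 1, 1)), 0)
  expect_equal(cut_value(gp, c(0, 0, 0)), 0)

  set.seed(5)
  W8 <- matrix(runif(64), 8, 8); W8 <- (W8 + t(W8)) / 2; diag(W8) <- 1
  g8 <- make_test_graph(W8, c(2, 4))
  for (i in 1:20) {
    u <- rbinom(8, 1, 0.5)
    expect_equal(cut_value(g8, u), graph_quadratic(g8, u), tolerance = 1e-12)
  }
  expect_error(cut_value(g8, c(0.5, rep(0, 7))), "binary")

  # exhaustive over all labelings of a 12-node graph
  W12 <- matrix(runif(144), 12, 12); W12 <- (W12 + t(W12)) / 2; diag(W12) <- 1
  g12 <- make_test_graph(W12, c(3, 4))
  worst <- 0
  for (m in 0:(2^12 - 1)) {
    u <- as.numeric(bitwAnd(m, 2^(0:11)) > 0)
    worst <- max(worst, abs(cut_value(g12, u) - graph_quadratic(g12, u)))
  }
  expect_lt(worst, 1e-12)
})

test_that("total variation counts boundary length with forward differences", {
  expect_equal(tv_norm(matrix(3, 6, 6)), 0)
  # two flat halves: four unit horizontal jumps
  u <- cbind(matrix(0, 4, 2), matrix(1, 4, 2))
  expect_equal(tv_norm(u), 4)
  set.seed(8)
  r <- matrix(rnorm(36), 6, 6)
  expect_equal(tv_norm(2.5 * r), 2.5 * tv_norm(r), tolerance = 1e-12)
  expect_equal(tv_norm(r), tv_dense(r))  # independent implementation
})

test_that("edge list export round-trips the stored weights", {
  g <- build_graph(us_image(matrix(1:16 + 0, 4, 4)), graph_config(window_radius = 1))
  df <- graph_edge_list(g)
  expect_setequal(names(df), c("i", "j", "w"))
  expect_equal(nrow(df), length(g$weights@x))
  path <- tempfile(fileext = ".txt")
  graph_edge_list(g, path)
  back <- utils::read.table(path, header = TRUE)
  expect_equal(sort(back$w), sort(df$w))
})
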