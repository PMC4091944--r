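test_that("isotropic shrinkage matches its proximal definition", {
  # magnitude below threshold vanishes
  s <- shrink(list(x = matrix(0.3, 1, 1), y = matrix(0.4, 1, 1)), 1)
  expect_equal(s$x[1], 0); expect_equal(s$y[1], 0)
  # 1-D reduction
  s <- shrink(list(x = matrix(3, 1, 1), y = matrix(0, 1, 1)), 1)
  expect_equal(s$x[1], 2); expect_equal(s$y[1], 0)

  # brute-force proximal oracle: argmin_y t|y| + 0.5|y - x|^2 by grid search
  set.seed(4)
  for (i in 1:10) {
    x <- rnorm(2); t <- runif(1, 0.2, 2)
    s <- shrink(list(x = matrix(x[1], 1, 1), y = matrix(x[2], 1, 1)), t)
    grid <- seq(-3, 3, by = 0.01)
    obj <- outer(grid, grid, function(a, b)
      t * sqrt(a^2 + b^2) + 0.5 * ((a - x[1])^2 + (b - x[2])^2))
    best <- which(obj == min(obj), arr.ind = TRUE)[1, ]
    expect_lt(abs(s$x[1] - grid[best[1]]), 1.5e-2)
    expect_lt(abs(s$y[1] - grid[best[2]]), 1.5e-2)
    # and the solver value is at least as good as the best grid point
    val <- t * sqrt(s$x[1]^2 + s$y[1]^2) +
      0.5 * ((s$x[1] - x[1])^2 + (s$y[1] - x[2])^2)
    expect_lte(val, min(obj) + 1e-9)
  }
})

test_that("DCT screened-Poisson solve equals a dense direct solve", {
  set.seed(7)
  nr <- 8; nc <- 8
  r1 <- 1.3; r2 <- 0.7
  A <- screened_poisson_dense(nr, nc, r1, r2)
  u <- matrix(rnorm(nr * nc), nr, nc); mu1 <- matrix(rnorm(nr * nc), nr, nc)
  d <- list(x = matrix(rnorm(nr * nc), nr, nc), y = matrix(rnorm(nr * nc), nr, nc))
  mu2 <- list(x = matrix(rnorm(nr * nc), nr, nc), y = matrix(rnorm(nr * nc), nr, nc))
  v <- solve_v_subproblem(u, mu1, d, mu2, r1, r2)
  rhs <- r1 * (u + mu1) - r2 * div_dense(d$x - mu2$x, d$y - mu2$y)
  v_dense <- matrix(solve(A, as.vector(rhs)), nr, nc)
  expect_lt(max(abs(v - v_dense)), 1e-8)

  # constants: d = mu2 and constant u + mu1 force a constant solution
  vc <- solve_v_subproblem(matrix(2, 5, 6), matrix(1, 5, 6),
                           d = list(x = matrix(3, 5, 6), y = matrix(-1, 5, 6)),
                           mu2 = list(x = matrix(3, 5, 6), y = matrix(-1, 5, 6)),
                           r1 = 2, r2 = 5)
  expect_equal(as.vector(vc), rep(3, 30), tolerance = 1e-10)
})

test_that("gradient and divergence are numerically adjoint", {
  set.seed(9)
  for (i in 1:10) {
    a <- matrix(rnorm(48), 6, 8)
    bx <- matrix(rnorm(48), 6, 8); by <- matrix(rnorm(48), 6, 8)
    g <- patchcut:::grad_forward(a)
    dv <- patchcut:::div_backward(bx, by)
    lhs <- sum(g$x * bx + g$y * by)
    rhs <- -sum(a * dv)
    expect_lt(abs(lhs - rhs), 1e-10)
  }
})

test_that("CG graph subproblem matches a dense direct solve and honors labels", {
  set.seed(12)
  # empty graph: identity system reduces to clipping
  W0 <- diag(6); g0 <- make_test_graph(W0, c(2, 3))
  v <- rnorm(6); mu1 <- rnorm(6)
  u <- solve_u_subproblem(g0, v, mu1, r1 = 2, labels = NULL)
  expect_equal(as.vector(u), pmin(pmax(v - mu1, 0), 1), tolerance = 1e-10)

  # dense oracle on random graphs up to 50 nodes, before projection
  for (n in c(6, 20, 50)) {
    W <- matrix(runif(n * n), n, n); W <- (W + t(W)) / 2; diag(W) <- 1
    gp <- make_test_graph(W, c(1, n))
    L <- diag(rowSums(W)) - W
    v <- rnorm(n); mu1 <- rnorm(n); r1 <- 1.7
    ucg <- solve_u_subproblem(gp, v, mu1, r1, labels = NULL,
                              cg_tol = 1e-12, project = FALSE)
    udense <- solve(2 * L + r1 * diag(n), r1 * (v - mu1))
    expect_lt(max(abs(ucg - udense)), 1e-8)
  }

  # labels imposed exactly after projection
  gp <- make_test_graph(two_cluster_graph(2, 3)$W, c(2, 3))
  lb <- label_set(foreground = 1L, background = 6L)
  u <- solve_u_subproblem(gp, rnorm(6), rnorm(6), 1, lb)
  expect_equal(u[1], 1); expect_equal(u[6], 0)
  expect_true(all(u >= 0 & u <= 1))
})

test_that("energy combines the graph quadratic and the TV term and is convex", {
  set.seed(15)
  img <- us_image(matrix(runif(64, 0, 255), 8, 8))
  g <- build_graph(img, graph_config(window_radius = 2))
  expect_equal(energy(matrix(0.4, 8, 8), g, lambda = 0.3), 0, tolerance = 1e-12)

  u <- matrix(rbinom(64, 1, 0.5), 8, 8)
  expect_equal(energy(u, g, 0.25),
               cut_value(g, as.vector(u)) + 0.25 * tv_norm(u),
               tolerance = 1e-10)

  for (i in 1:20) {
    a <- matrix(runif(64), 8, 8); b <- matrix(runif(64), 8, 8)
    expect_lte(energy((a + b) / 2, g, 0.2),
               (energy(a, g, 0.2) + energy(b, g, 0.2)) / 2 + 1e-10)
  }
})

test_that("binarize thresholds, forces labels, and is idempotent", {
  u <- matrix(1, 4, 4)
  expect_true(all(binarize(u) == 1))
  lb <- label_set(foreground = 5L)
  u2 <- matrix(0.5 - 1e-9, 4, 4)
  m <- binarize(u2, 0.5, lb)
  expect_equal(sum(m), 1); expect_equal(m[5], 1L)
  expect_equal(binarize(m + 0, 0.5, lb), m)
})

test_that("fully labeled problems return the labels verbatim in one iteration", {
  g <- build_graph(us_image(matrix(50, 4, 4)), graph_config(window_radius = 1))
  lb <- label_set(foreground = 1:8, background = 9:16)
  sol <- solve_cmc(g, lb)
  expect_equal(sol$iterations, 1L)
  expect_equal(as.vector(sol$mask), rep(c(1L, 0L), each = 8))
})

test_that("the solver is deterministic and feasible after every outer iteration", {
  ph <- small_phantom()
  g <- build_graph(ph$image)
  lb <- to_label_set(ph$label_map)
  s1 <- solve_cmc(g, lb)
  s2 <- solve_cmc(g, lb)
  expect_identical(s1$mask, s2$mask)
  expect_identical(s1$u, s2$u)

  for (k in c(1L, 3L, 10L)) {
    sk <- solve_cmc(g, lb, solver_params(max_outer = k))
    expect_true(all(sk$u >= 0 & sk$u <= 1))
    expect_true(all(sk$u[lb$foreground] == 1))
    expect_true(all(sk$u[lb$background] == 0))
  }
})

test_that("splitting residuals fall below tolerance and do not increase at the end", {
  ph <- small_phantom()
  fit <- patchcut(ph$image, ph$label_map)
  expect_true(fit$converged)
  h <- fit$history
  n <- nrow(h)
  expect_lt(h$res_uv[n], 1e-3)
  expect_lt(h$res_gd[n], 1e-3)
  last10 <- utils::tail(pmax(h$res_uv, h$res_gd), 10)
  expect_true(all(diff(last10) <= 1e-6))
})

test_that("tiny label-constrained problems reach the exhaustive binary optimum", {
  lam <- 0.05
  n_attained <- 0
  for (seed in 1:8) {
    tc <- two_cluster_graph(3, 4, seed = seed)
    gp <- make_test_graph(tc$W, c(3, 4))
    fg <- which(!tc$cluster)[1]; bg <- which(tc$cluster)[1]
    lb <- label_set(fg, bg)
    sol <- solve_cmc(gp, lb, solver_params(lambda = lam, max_outer = 8000,
                                           outer_tol = 1e-8, residual_tol = 1e-7))
    oracle <- exhaustive_binary_optimum(tc$W, c(3, 4), lam, fg, bg)
    relaxed_energy <- energy(sol$u, gp, lam)
    expect_lte(relaxed_energy, oracle$energy + 1e-6)
    cut_sol <- cut_value(gp, as.vector(sol$mask))
    if (abs(cut_sol - oracle$cut) < 1e-8) n_attained <- n_attained + 1
  }
  # well-separated clusters: the threshold recovers the exact minimum cut
  expect_equal(n_attained, 8)
})
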