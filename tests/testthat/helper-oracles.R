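# Independent oracles and small fixtures used across the suite.
# Everything here is deliberately written from first principles (dense
# linear algebra, exhaustive enumeration) rather than through the package's
# own solver paths.

dice <- function(a, b) {
  a <- a != 0; b <- b != 0
  if (sum(a) + sum(b) == 0) return(1)
  2 * sum(a & b) / (sum(a) + sum(b))
}

# wrap an arbitrary symmetric weight matrix as a patch_graph over a grid
make_test_graph <- function(W, shape) {
  W <- Matrix::Matrix(W, sparse = TRUE)
  W <- methods::as(W, "generalMatrix")
  deg <- Matrix::rowSums(W)
  structure(list(weights = W,
                 laplacian = methods::as(Matrix::Diagonal(x = deg) - W,
                                         "generalMatrix"),
                 n_nodes = nrow(W), image_shape = shape,
                 mean_degree = mean(deg), config = graph_config()),
            class = "patch_graph")
}

# random symmetric two-cluster weight matrix on an nr x nc grid; the clusters
# are the left and right halves of the grid
two_cluster_graph <- function(nr, nc, intra = c(0.5, 1), inter = c(0.005, 0.05),
                              seed = 1) {
  set.seed(seed)
  n <- nr * nc
  cl <- rep(seq_len(nc) > nc / 2, each = nr)  # column-major
  W <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    rng <- if (cl[i] == cl[j]) intra else inter
    W[i, j] <- W[j, i] <- stats::runif(1, rng[1], rng[2])
  }
  diag(W) <- 1
  list(W = W, cluster = cl)
}

# dense TV of a field on a grid: forward differences, replicate boundary
tv_dense <- function(u) {
  nr <- nrow(u); nc <- ncol(u)
  gx <- cbind(u[, -1, drop = FALSE] - u[, -nc, drop = FALSE], 0)
  gy <- rbind(u[-1, , drop = FALSE] - u[-nr, , drop = FALSE], 0)
  sum(sqrt(gx^2 + gy^2))
}

# exhaustive minimum of cut + lambda*TV over binary masks that satisfy the
# labels; masks live on an nr x nc grid in column-major order
exhaustive_binary_optimum <- function(W, shape, lambda, fg, bg) {
  n <- nrow(W)
  L <- diag(rowSums(W)) - W
  free <- setdiff(seq_len(n), c(fg, bg))
  stopifnot(length(free) <= 16)
  best <- Inf; best_u <- NULL; best_cut <- Inf
  for (m in 0:(2^length(free) - 1)) {
    u <- numeric(n); u[fg] <- 1
    if (length(free)) u[free] <- as.numeric(bitwAnd(m, 2^(seq_along(free) - 1)) > 0)
    cutv <- as.numeric(t(u) %*% L %*% u)
    e <- cutv + lambda * tv_dense(matrix(u, shape[1], shape[2]))
    if (e < best) { best <- e; best_u <- u; best_cut <- cutv }
  }
  list(energy = best, u = best_u, cut = best_cut)
}

# dense 1D Neumann Laplacian (second difference with reflecting ends)
neumann_1d <- function(n) {
  T <- matrix(0, n, n)
  for (i in seq_len(n)) {
    T[i, i] <- -2
    if (i > 1) T[i, i - 1] <- 1
    if (i < n) T[i, i + 1] <- 1
  }
  T[1, 1] <- -1; T[n, n] <- -1
  T
}

# dense operator of the screened Poisson problem on an nr x nc grid,
# column-major vectorization: r1*I - r2*(I (x) T_r + T_c (x) I)
screened_poisson_dense <- function(nr, nc, r1, r2) {
  Tr <- neumann_1d(nr); Tc <- neumann_1d(nc)
  lap <- kronecker(diag(nc), Tr) + kronecker(Tc, diag(nr))
  r1 * diag(nr * nc) - r2 * lap
}

# independent divergence with the package's documented convention:
# negative adjoint of the forward-difference gradient (last col/row ignored)
div_dense <- function(p, q) {
  nr <- nrow(p); nc <- ncol(p)
  p[, nc] <- 0; q[nr, ] <- 0
  (p - cbind(0, p[, -nc, drop = FALSE])) + (q - rbind(0, q[-nr, , drop = FALSE]))
}

# a small, fast disk phantom for solver tests (64 x 64, radius 15)
small_phantom <- function(seed = 0) {
  ph <- make_phantom(shape = c(64, 64), semi_axes = c(15, 15),
                     fg_level = 140, bg_level = 60, sigma_noise = 1.5,
                     seed = seed)
  lm <- label_map(c(64, 64))
  lm <- label_line(lm, c(32, 28), c(32, 38), code = 1L)
  lm <- label_line(lm, c(6, 10), c(6, 50), code = 2L)
  list(image = ph$image, ground_truth = ph$ground_truth, label_map = lm)
}
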