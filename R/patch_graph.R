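#' Graph construction parameters
#'
#' @param patch_radius integer >= 0; the patch is a (2r+1) x (2r+1) square of
#'   intensities centered on each pixel.  Patch size should match the speckle
#'   texture scale; radius 1 (3x3) keeps fine detail and is fast.
#' @param window_radius integer >= 1; edges connect each pixel to every pixel
#'   in a (2R+1) x (2R+1) search window (clipped at the image border).
#' @param sigma positive kernel bandwidth.  It plays the role of the typical
#'   patch distance between patches of the same tissue: weights are
#'   `exp(-d / sigma^2)`.  The default 3 is calibrated on the 0..255 intensity
#'   scale so that the median within-region weight on the bundled disk phantom
#'   is about 0.6.
#' @param eps small positive guard for zero denominators in the patch distance.
#' @param symmetric use the symmetrized chi-square denominator `(p+q)/2`
#'   (default); `FALSE` selects the asymmetric variant with denominator `q`.
#' @return an object of class `graph_config`.
#' @export
graph_config <- function(patch_radius = 1L, window_radius = 5L, sigma = 3,
                         eps = 1e-6, symmetric = TRUE) {
  patch_radius <- as.integer(patch_radius)
  window_radius <- as.integer(window_radius)
  stopifnot(patch_radius >= 0L, window_radius >= 1L, sigma > 0, eps > 0)
  structure(list(patch_radius = patch_radius, window_radius = window_radius,
                 sigma = sigma, eps = eps, symmetric = isTRUE(symmetric)),
            class = "graph_config")
}

#' @export
#' @method print graph_config
print.graph_config <- function(x, ...) {
  cat(sprintf("graph_config: patch %dx%d, window %dx%d, sigma %.3g, eps %.1e\n",
              2 * x$patch_radius + 1, 2 * x$patch_radius + 1,
              2 * x$window_radius + 1, 2 * x$window_radius + 1, x$sigma, x$eps))
  invisible(x)
}

# mirror-reflected index vector 1-r .. n+r for border padding
reflect_index <- function(n, r) {
  i <- seq(1 - r, n + r)
  i <- abs(i - 1) %% (2 * n)
  ifelse(i < n, i + 1, 2 * n - i)
}

mirror_pad <- function(m, r) {
  if (r == 0L) return(m)
  m[reflect_index(nrow(m), r), reflect_index(ncol(m), r), drop = FALSE]
}

#' Extract a square intensity patch around a pixel
#'
#' Out-of-image samples are filled by mirror reflection across the border, so
#' border patches carry no artificial intensity jumps.
#'
#' @param image a [us_image] or numeric matrix.
#' @param center integer length-2 (row, col) pixel position.
#' @param patch_radius integer >= 0.
#' @return numeric vector of (2r+1)^2 intensities in column-major order
#'   (rows vary fastest), matching R matrix layout.
#' @export
extract_patch <- function(image, center, patch_radius = 1L) {
  m <- as_intensity_matrix(image)
  r <- as.integer(patch_radius)
  stopifnot(r >= 0L)
  cr <- as.integer(center[1]); cc <- as.integer(center[2])
  if (cr < 1L || cr > nrow(m) || cc < 1L || cc > ncol(m))
    stop("patch center outside image")
  ri <- reflect_index(nrow(m), r)[(cr - r):(cr + r) + r]
  ci <- reflect_index(ncol(m), r)[(cc - r):(cc + r) + r]
  as.vector(m[ri, ci, drop = FALSE])
}

#' Speckle-adapted (chi-square/Pearson) distance between patches
#'
#' `d(p, q) = (1/N) * sum (p_k - q_k)^2 / max((p_k + q_k)/2, eps)`.
#' Normalizing squared differences by local intensity matches speckle whose
#' variance grows in proportion to the mean, so equally-similar patches get
#' equal distances in bright and dark tissue alike.  The distance is
#' symmetric, nonnegative, zero iff `p == q`, and scale-equivariant:
#' `d(a*p, a*q) = a * d(p, q)` for `a > 0` (as `eps -> 0`).
#'
#' @param p,q equal-length nonnegative numeric vectors.
#' @param eps positive denominator guard.
#' @param symmetric use denominator `(p+q)/2` (default) or `q` (asymmetric,
#'   non-local-means style).
#' @return nonnegative scalar.
#' @export
pearson_distance <- function(p, q, eps = 1e-6, symmetric = TRUE) {
  if (length(p) != length(q)) stop("patch length mismatch")
  if (length(p) < 1L) stop("empty patches")
  if (any(p < 0) || any(q < 0)) stop("patch intensities must be nonnegative")
  den <- if (symmetric) (p + q) / 2 else q
  mean((p - q)^2 / pmax(den, eps))
}

#' Build the patch similarity graph of an image
#'
#' Every pixel is connected to every pixel in its search window; the edge
#' weight is `exp(-d(P_i, P_j) / sigma^2)` with `d` the patch distance of
#' [pearson_distance()].  The window relation is symmetric and windows are
#' clipped at the image border, so the weight matrix is symmetric by
#' construction and only connects real pixels.  Self-weights (1) are stored;
#' they cancel in the Laplacian and in cuts.
#'
#' @param image a [us_image] or nonnegative numeric matrix.
#' @param config a [graph_config].
#' @return an object of class `patch_graph`: list with `weights` (sparse
#'   symmetric dgCMatrix), `laplacian` (`D - W`), `n_nodes`, `image_shape`,
#'   `mean_degree` and the `config` used.  Pixel i is `(col-1)*nrows + row`.
#' @export
build_graph <- function(image, config = graph_config()) {
  m <- as_intensity_matrix(image)
  if (any(m < 0)) stop("intensities must be nonnegative")
  nr <- nrow(m); nc <- ncol(m); n <- nr * nc
  R <- config$patch_radius; Wr <- config$window_radius
  P <- mirror_pad(m, R)
  npatch <- (2 * R + 1)^2
  offs <- expand.grid(dr = -Wr:Wr, dc = 0:Wr)
  offs <- offs[offs$dc > 0 | (offs$dc == 0 & offs$dr > 0), , drop = FALSE]
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  ii <- jj <- xx <- vector("list", nrow(offs))
  for (k in seq_len(nrow(offs))) {
    a <- offs$dr[k]; b <- offs$dc[k]
    r1 <- max(1, 1 - a); r2 <- min(nr, nr - a)
    c1 <- max(1, 1 - b); c2 <- min(nc, nc - b)
    if (r1 > r2 || c1 > c2) next
    acc <- 0
    for (s in -R:R) for (t in -R:R) {
      p <- P[(r1 + s + R):(r2 + s + R), (c1 + t + R):(c2 + t + R), drop = FALSE]
      q <- P[(r1 + a + s + R):(r2 + a + s + R), (c1 + b + t + R):(c2 + b + t + R), drop = FALSE]
      den <- if (config$symmetric) (p + q) / 2 else q
      acc <- acc + (p - q)^2 / pmax(den, config$eps)
    }
    w <- exp(-(acc / npatch) / config$sigma^2)
    sel_r <- r1:r2; sel_c <- c1:c2
    i_idx <- (cols[sel_r, sel_c, drop = FALSE] - 1L) * nr + rows[sel_r, sel_c, drop = FALSE]
    ii[[k]] <- as.vector(i_idx)
    jj[[k]] <- as.vector(i_idx + b * nr + a)
    xx[[k]] <- as.vector(w)
  }
  i <- unlist(ii); j <- unlist(jj); x <- unlist(xx)
  W <- Matrix::sparseMatrix(i = c(i, j, seq_len(n)), j = c(j, i, seq_len(n)),
                            x = c(x, x, rep(1, n)), dims = c(n, n))
  deg <- Matrix::rowSums(W)
  L <- Matrix::Diagonal(x = deg) - W
  structure(list(weights = W,
                 laplacian = methods::as(L, "generalMatrix"),
                 n_nodes = n, image_shape = c(nr, nc),
                 mean_degree = mean(deg), config = config),
            class = "patch_graph")
}

#' @export
#' @method print patch_graph
print.patch_graph <- function(x, ...) {
  cat(sprintf("patch_graph: %d nodes (%d x %d), %d stored edges, mean degree %.2f\n",
              x$n_nodes, x$image_shape[1], x$image_shape[2],
              length(x$weights@x), x$mean_degree))
  invisible(x)
}

#' Weight of the cut induced by a binary labeling
#'
#' Sums `w_ij` over unordered pixel pairs with `u_i = 1, u_j = 0`.  For binary
#' `u` this equals the Laplacian quadratic form [graph_quadratic()].
#'
#' @param graph a [patch_graph] (or any list with a `weights` sparse matrix).
#' @param indicator binary vector (0/1), one entry per node.
#' @return nonnegative scalar cut weight.
#' @export
cut_value <- function(graph, indicator) {
  u <- as.numeric(indicator)
  if (length(u) != nrow(graph$weights)) stop("indicator length mismatch")
  if (!all(u %in% c(0, 1))) stop("indicator must be binary")
  a <- which(u == 1)
  if (length(a) == 0L || length(a) == length(u)) return(0)
  sum(graph$weights[a, -a, drop = FALSE])
}

#' Graph Laplacian quadratic form
#'
#' `u' L u = 1/2 * sum_ij w_ij (u_i - u_j)^2`; the relaxed graph term of the
#' segmentation energy.  Nonnegative for any real `u`, zero on constants, and
#' equal to [cut_value()] when `u` is binary.
#'
#' @param graph a [patch_graph].
#' @param u numeric vector, one entry per node.
#' @return nonnegative scalar.
#' @export
graph_quadratic <- function(graph, u) {
  u <- as.numeric(u)
  if (length(u) != nrow(graph$laplacian)) stop("size mismatch")
  as.numeric(t(u) %*% (graph$laplacian %*% u))
}

# forward-difference gradient with replicate (Neumann) boundary:
# zero in the last column (x) / last row (y)
grad_forward <- function(u) {
  nr <- nrow(u); nc <- ncol(u)
  gx <- cbind(u[, -1, drop = FALSE] - u[, -nc, drop = FALSE], 0)
  gy <- rbind(u[-1, , drop = FALSE] - u[-nr, , drop = FALSE], 0)
  list(x = gx, y = gy)
}

# negative adjoint of grad_forward; the last column of p / last row of q are
# outside the range of the gradient and are ignored
div_backward <- function(p, q) {
  nr <- nrow(p); nc <- ncol(p)
  p[, nc] <- 0; q[nr, ] <- 0
  (p - cbind(0, p[, -nc, drop = FALSE])) + (q - rbind(0, q[-nr, , drop = FALSE]))
}

#' Isotropic total variation of a field on the image grid
#'
#' Forward differences with replicate (Neumann) boundary;
#' `sum_pixels sqrt(gx^2 + gy^2)`.  Penalizes the length of level-line
#' boundaries and so smooths the segmentation contour.
#'
#' @param u numeric matrix.
#' @return nonnegative scalar.
#' @export
tv_norm <- function(u) {
  u <- as_intensity_matrix(u)
  g <- grad_forward(u)
  sum(sqrt(g$x^2 + g$y^2))
}

#' Export the stored edges of a graph as a 3-column table
#'
#' @param graph a [patch_graph].
#' @param path optional path; when given, writes a whitespace-separated
#'   `i j w` text file.
#' @return data.frame with columns `i`, `j`, `w` (invisibly when writing).
#' @export
graph_edge_list <- function(graph, path = NULL) {
  s <- Matrix::summary(graph$weights)
  df <- data.frame(i = s$i, j = s$j, w = s$x)
  if (!is.null(path)) {
    utils::write.table(df, path, row.names = FALSE, quote = FALSE)
    return(invisible(df))
  }
  df
}
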