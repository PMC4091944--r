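#' Solver parameters for the relaxed min-cut energy
#'
#' The energy is `E(u) = u' L u + lambda * TV(u)` minimized over membership
#' fields `u` in `[0,1]^n` with hard label constraints, via augmented-Lagrangian
#' splitting: `v` duplicates `u` (penalty `r1`), `d` duplicates the gradient of
#' `v` (penalty `r2`), and a third copy `w` of `u` carries the box-and-label
#' constraint (penalty tied to `r1`); see [solve_cmc()].
#'
#' @param lambda positive TV weight; controls contour smoothness and removes
#'   small misclassified pixel sets.  Default 0.1.
#' @param r1,r2 positive augmented-Lagrangian penalties.  `NULL` (default)
#'   sets both to the mean weighted degree of the graph, which matches the
#'   penalty to the scale of the graph operator; penalties only affect
#'   convergence speed, not the minimizer.
#' @param relax over-relaxation factor in (0, 2); 1 disables.  Default 1.8.
#' @param cg_tol,cg_maxiter relative-residual tolerance and iteration cap for
#'   the conjugate-gradient graph subproblem.
#' @param outer_tol stopping tolerance on the relative change of successive
#'   `u` iterates.
#' @param residual_tol stopping tolerance on the RMS splitting residuals
#'   `|u - v|`, `|grad v - d|` and `|u - w|`.
#' @param max_outer cap on outer iterations.
#' @param threshold binarization threshold in (0, 1) for the final mask.
#' @return object of class `solver_params`.
#' @export
solver_params <- function(lambda = 0.1, r1 = NULL, r2 = NULL, relax = 1.8,
                          cg_tol = 1e-6, cg_maxiter = 200L,
                          outer_tol = 2e-4, residual_tol = 1e-3,
                          max_outer = 2000L, threshold = 0.5) {
  stopifnot(lambda > 0, is.null(r1) || r1 > 0, is.null(r2) || r2 > 0,
            relax > 0, relax < 2 + 1e-12,
            cg_tol > 0, cg_maxiter >= 1, outer_tol > 0, residual_tol > 0,
            max_outer >= 1, threshold > 0, threshold < 1)
  structure(list(lambda = lambda, r1 = r1, r2 = r2, relax = relax,
                 cg_tol = cg_tol, cg_maxiter = as.integer(cg_maxiter),
                 outer_tol = outer_tol, residual_tol = residual_tol,
                 max_outer = as.integer(max_outer), threshold = threshold),
            class = "solver_params")
}

#' @export
#' @method print solver_params
print.solver_params <- function(x, ...) {
  cat(sprintf(paste0("solver_params: lambda %.3g, r1 %s, r2 %s, relax %.2g, ",
                     "outer_tol %.1e, residual_tol %.1e, max_outer %d, threshold %.2f\n"),
              x$lambda, if (is.null(x$r1)) "auto" else format(x$r1),
              if (is.null(x$r2)) "auto" else format(x$r2),
              x$relax, x$outer_tol, x$residual_tol, x$max_outer, x$threshold))
  invisible(x)
}

#' Foreground/background label constraints
#'
#' @param foreground integer pixel indices constrained to u = 1 (at least one).
#' @param background integer pixel indices constrained to u = 0 (may be empty).
#' @return object of class `label_set`.
#' @export
label_set <- function(foreground, background = integer(0)) {
  foreground <- sort(unique(as.integer(foreground)))
  background <- sort(unique(as.integer(background)))
  if (length(foreground) == 0L) stop("at least one foreground label is required")
  if (length(intersect(foreground, background)) > 0L)
    stop("foreground and background labels must be disjoint")
  structure(list(foreground = foreground, background = background),
            class = "label_set")
}

#' @export
#' @method print label_set
print.label_set <- function(x, ...) {
  cat(sprintf("label_set: %d foreground, %d background pixels\n",
              length(x$foreground), length(x$background)))
  invisible(x)
}

#' Relaxed segmentation energy
#'
#' `E(u) = u' L u + lambda * TV(u)`.  Convex in `u`; for binary `u` the graph
#' term equals the cut weight.
#'
#' @param u numeric matrix on the image grid (or vector of matching length).
#' @param graph a [patch_graph].
#' @param lambda positive TV weight.
#' @return scalar energy.
#' @export
energy <- function(u, graph, lambda = 0.1) {
  shp <- graph$image_shape
  if (length(u) != graph$n_nodes) stop("size mismatch")
  um <- matrix(as.numeric(u), shp[1], shp[2])
  graph_quadratic(graph, as.vector(um)) + lambda * tv_norm(um)
}

#' Graph (membership) subproblem
#'
#' Solves `(2L + r1 I) u = r1 (v - mu1)` by warm-started conjugate gradient,
#' then (optionally) projects: clips to `[0,1]` and imposes the labels exactly.
#'
#' @param graph a [patch_graph].
#' @param v,mu1 split field and multiplier (matrices or vectors).
#' @param r1 positive penalty.
#' @param labels a [label_set], or `NULL` for no constraints.
#' @param cg_tol,cg_maxiter CG control.
#' @param u0 warm start (defaults to zeros).
#' @param project clip to the box and impose labels (default `TRUE`).
#' @return numeric vector `u`; attribute `cg_iterations`.
#' @export
solve_u_subproblem <- function(graph, v, mu1, r1, labels = NULL,
                               cg_tol = 1e-6, cg_maxiter = 200L,
                               u0 = NULL, project = TRUE) {
  L <- graph$laplacian
  b <- r1 * (as.numeric(v) - as.numeric(mu1))
  if (is.null(u0)) u0 <- numeric(length(b))
  res <- .cg_graph_solve(L@p, L@i, L@x, b, as.numeric(u0),
                         r1, cg_tol, as.integer(cg_maxiter))
  if (!res$converged)
    warning("conjugate gradient did not reach tolerance in ", cg_maxiter,
            " iterations; using last iterate")
  u <- res$x
  if (project) {
    u <- pmin(pmax(u, 0), 1)
    if (!is.null(labels)) {
      u[labels$foreground] <- 1
      u[labels$background] <- 0
    }
  }
  attr(u, "cg_iterations") <- res$iterations
  u
}

# orthonormal DCT-II matrix cache; eigenvectors of the Neumann 1D Laplacian
.dct_cache <- new.env(parent = emptyenv())
dct_matrix <- function(n) {
  key <- as.character(n)
  if (!is.null(.dct_cache[[key]])) return(.dct_cache[[key]])
  k <- 0:(n - 1)
  C <- sqrt(2 / n) * cos(pi * outer(k, k + 0.5) / n)
  C[1, ] <- C[1, ] / sqrt(2)
  .dct_cache[[key]] <- C
  C
}

# eigenvalues of minus the 1D Neumann Laplacian under DCT-II
neumann_eigenvalues <- function(n) 4 * sin(pi * (0:(n - 1)) / (2 * n))^2

#' Field (screened Poisson) subproblem
#'
#' Solves `(r1 I - r2 Lap) v = r1 (u + mu1) - r2 div(d - mu2)` with Neumann
#' (replicate) boundary, where `Lap = div o grad` is the 5-point Laplacian
#' built from the forward-difference gradient of [tv_norm()] and `div` is its
#' negative adjoint.  Diagonalized exactly by the orthonormal DCT-II.
#'
#' @param u,mu1 field and multiplier matrices.
#' @param d,mu2 2-component split gradient and multiplier: lists with `x`, `y`.
#' @param r1,r2 positive penalties.
#' @return matrix `v`.
#' @export
solve_v_subproblem <- function(u, mu1, d, mu2, r1, r2) {
  nr <- nrow(u); nc <- ncol(u)
  rhs <- r1 * (u + mu1) - r2 * div_backward(d$x - mu2$x, d$y - mu2$y)
  Cr <- dct_matrix(nr); Cc <- dct_matrix(nc)
  den <- r1 + r2 * outer(neumann_eigenvalues(nr), rep(1, nc)) +
              r2 * outer(rep(1, nr), neumann_eigenvalues(nc))
  crossprod(Cr, ((Cr %*% rhs %*% t(Cc)) / den)) %*% Cc
}

#' Isotropic soft-thresholding (vectorial shrinkage)
#'
#' Per-pixel proximal operator of `t * |.|` on 2-vectors:
#' `y = x * max(|x| - t, 0) / |x|`.
#'
#' @param x list with matrices `x` and `y` (the two gradient components).
#' @param t positive threshold.
#' @return list with shrunk components `x`, `y`.
#' @export
shrink <- function(x, t) {
  stopifnot(t > 0)
  mag <- sqrt(x$x^2 + x$y^2)
  fac <- pmax(mag - t, 0) / pmax(mag, 1e-12)
  list(x = x$x * fac, y = x$y * fac)
}

#' Threshold a membership field to a binary mask
#'
#' `mask = (u >= threshold)`, with foreground labels forced to 1 and
#' background labels to 0.
#'
#' @param u numeric matrix (or vector) membership field.
#' @param threshold scalar in (0, 1).
#' @param labels a [label_set] or `NULL`.
#' @return integer 0/1 matrix of the same shape as `u`.
#' @export
binarize <- function(u, threshold = 0.5, labels = NULL) {
  stopifnot(threshold > 0, threshold < 1)
  mk <- (as_intensity_matrix(u) >= threshold) + 0L
  if (!is.null(labels)) {
    mk[labels$foreground] <- 1L
    mk[labels$background] <- 0L
  }
  mk
}

#' Minimize the relaxed min-cut energy on a prebuilt graph
#'
#' Augmented-Lagrangian splitting with three auxiliary copies: `v`
#' duplicates the membership `u` for the TV coupling (penalty `r1`), `d`
#' duplicates the gradient of `v` (penalty `r2`), and `w` duplicates `u` for
#' the box-and-label constraint (penalty `r1` again), so that every
#' subproblem is solved *exactly*: (1) an unconstrained CG solve of the
#' graph system, (2) a DCT screened-Poisson solve for `v`, (3) isotropic
#' shrinkage for `d`, (4) projection onto `[0,1]` with labels imposed for
#' `w`, then multiplier ascent.  Carrying the constraint on its own splitting
#' variable (rather than clipping the CG solution in place) makes the
#' projection the exact proximal step of the constraint indicator, so the
#' iteration converges to the true constrained minimizer instead of a
#' nearby biased fixed point.  Stops when the relative change of the
#' feasible iterate and all RMS splitting residuals fall under their
#' tolerances.  Deterministic: no randomness anywhere.
#'
#' @param graph a [patch_graph] over the pixels of the image grid.
#' @param labels a [label_set] with pixel indices into the grid.
#' @param params a [solver_params].
#' @param init initial membership: `"labels"` (zeros with 1 on foreground,
#'   default), `"zeros"`, or `"ones"`.  By convexity the solution does not
#'   depend on this choice; it only affects iteration count.
#' @return list with `u` (the feasible membership matrix in `[0,1]`), `mask`
#'   (0/1 matrix), `v`, `d`, `mu1`, `mu2`, `mu3` (splitting state),
#'   `iterations`, `converged`, and `history` (per-iteration energy, relative
#'   change, residuals).
#' @export
solve_cmc <- function(graph, labels, params = solver_params(),
                      init = c("labels", "zeros", "ones")) {
  init <- match.arg(init)
  shp <- graph$image_shape
  nr <- shp[1]; nc <- shp[2]; n <- graph$n_nodes
  if (length(labels$foreground) == 0L) stop("empty foreground")
  if (max(c(labels$foreground, labels$background)) > n)
    stop("label index outside image")
  r1 <- if (is.null(params$r1)) graph$mean_degree else params$r1
  r2 <- if (is.null(params$r2)) graph$mean_degree else params$r2
  r3 <- r1   # constraint-copy penalty, tied to the u-consensus penalty

  nlab <- length(labels$foreground) + length(labels$background)
  if (nlab == n) {  # fully constrained: the labels are the answer
    u <- numeric(n); u[labels$foreground] <- 1
    um <- matrix(u, nr, nc)
    return(list(u = um, mask = binarize(um, params$threshold, labels),
                v = um, d = list(x = matrix(0, nr, nc), y = matrix(0, nr, nc)),
                mu1 = matrix(0, nr, nc),
                mu2 = list(x = matrix(0, nr, nc), y = matrix(0, nr, nc)),
                mu3 = numeric(n),
                iterations = 1L, converged = TRUE,
                history = data.frame(energy = energy(um, graph, params$lambda),
                                     rel_change = 0, res_uv = 0, res_gd = 0,
                                     res_uw = 0),
                r1 = r1, r2 = r2))
  }

  u <- switch(init,
              labels = { x <- numeric(n); x[labels$foreground] <- 1; x },
              zeros = numeric(n),
              ones = rep(1, n))
  if (init != "zeros") { u[labels$foreground] <- 1; u[labels$background] <- 0 }
  w <- u                       # feasible copy of u (box + labels)
  v <- matrix(u, nr, nc)
  d <- list(x = matrix(0, nr, nc), y = matrix(0, nr, nc))
  mu2 <- list(x = matrix(0, nr, nc), y = matrix(0, nr, nc))
  mu1 <- matrix(0, nr, nc)
  mu3 <- numeric(n)
  L <- graph$laplacian

  hist_energy <- hist_rel <- hist_r1 <- hist_r2 <- hist_r3 <- numeric(params$max_outer)
  converged <- FALSE
  k <- 0L
  while (k < params$max_outer) {
    k <- k + 1L
    wprev <- w
    # graph subproblem: (2L + (r1 + r3) I) u = r1 (v - mu1) + r3 (w - mu3)
    b <- r1 * as.vector(v - mu1) + r3 * (w - mu3)
    res <- .cg_graph_solve(L@p, L@i, L@x, b, u, r1 + r3,
                           params$cg_tol, params$cg_maxiter)
    if (!res$converged)
      warning("conjugate gradient did not reach tolerance; using last iterate")
    u <- res$x
    U <- matrix(u, nr, nc)
    Uh <- params$relax * U + (1 - params$relax) * v
    v <- solve_v_subproblem(Uh, mu1, d, mu2, r1, r2)
    g <- grad_forward(v)
    d <- shrink(list(x = g$x + mu2$x, y = g$y + mu2$y), params$lambda / r2)
    uh <- params$relax * u + (1 - params$relax) * w
    w <- pmin(pmax(uh + mu3, 0), 1)
    w[labels$foreground] <- 1
    w[labels$background] <- 0
    mu1 <- mu1 + (Uh - v)
    mu2$x <- mu2$x + (g$x - d$x)
    mu2$y <- mu2$y + (g$y - d$y)
    mu3 <- mu3 + (uh - w)

    rel <- sqrt(sum((w - wprev)^2)) / max(sqrt(sum(wprev^2)), 1e-12)
    res_uv <- sqrt(sum((U - v)^2)) / sqrt(n)
    res_gd <- sqrt(sum((g$x - d$x)^2 + (g$y - d$y)^2)) / sqrt(n)
    res_uw <- sqrt(sum((u - w)^2)) / sqrt(n)
    hist_energy[k] <- graph_quadratic(graph, w) +
      params$lambda * tv_norm(matrix(w, nr, nc))
    hist_rel[k] <- rel; hist_r1[k] <- res_uv; hist_r2[k] <- res_gd
    hist_r3[k] <- res_uw
    if (rel <= params$outer_tol &&
        max(res_uv, res_gd, res_uw) <= params$residual_tol) {
      converged <- TRUE
      break
    }
  }
  um <- matrix(w, nr, nc)
  list(u = um, mask = binarize(um, params$threshold, labels),
       v = v, d = d, mu1 = mu1, mu2 = mu2, mu3 = mu3,
       iterations = k, converged = converged,
       history = data.frame(energy = hist_energy[seq_len(k)],
                            rel_change = hist_rel[seq_len(k)],
                            res_uv = hist_r1[seq_len(k)],
                            res_gd = hist_r2[seq_len(k)],
                            res_uw = hist_r3[seq_len(k)]),
       r1 = r1, r2 = r2)
}
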