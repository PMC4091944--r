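#' Segment an ultrasound image from user scribbles
#'
#' The main fitting function.  Builds (or reuses) the patch similarity graph
#' of the image, then minimizes the relaxed min-cut energy
#' `u' L u + lambda * TV(u)` over membership fields `u` in `[0,1]` subject to
#' the user labels, and thresholds the result to a binary mask.  The energy is
#' convex, so the segmentation does not depend on the initialization.
#'
#' @param image a [us_image] (or nonnegative matrix).
#' @param labels a [label_set], or a label map matrix with codes 0 (unlabeled),
#'   1 (foreground), 2 (background) as produced by the `label_*` builders.
#' @param graph optional prebuilt [patch_graph] of `image` (e.g. from a
#'   previous fit on the same image); when supplied, graph construction is
#'   skipped so that re-segmentation with new scribbles is cheap.
#' @param config a [graph_config] (ignored when `graph` is given).
#' @param params a [solver_params].
#' @param init initialization of the membership field (see [solve_cmc()]).
#' @return An object of class `patchcut`: list with elements
#'   `mask` (0/1 matrix), `membership` (the relaxed field `u`), `labels`,
#'   `graph`, `params`, `iterations`, `converged`, `energy`, `history`, and
#'   `provenance` (all effective parameters).
#' @seealso [update.patchcut()] to re-segment with new labels without
#'   rebuilding the graph; [overlap()] to score against a reference mask;
#'   [head_biometry()] for fetal-head measurements.
#' @examples
#' ph <- default_phantom()
#' fit <- patchcut(ph$image, ph$label_map)
#' fit
#' overlap(fit$mask, ph$ground_truth)$dcm
#' @export
patchcut <- function(image, labels, graph = NULL, config = graph_config(),
                     params = solver_params(),
                     init = c("labels", "zeros", "ones")) {
  init <- match.arg(init)
  img <- if (inherits(image, "us_image")) image else us_image(image)
  if (is.matrix(labels)) labels <- to_label_set(labels)
  if (!inherits(labels, "label_set")) stop("labels must be a label_set or label map")
  if (is.null(graph)) {
    graph <- build_graph(img, config)
  } else {
    if (!inherits(graph, "patch_graph")) stop("graph must be a patch_graph")
    if (!all(graph$image_shape == dim(img)))
      stop("graph shape does not match image")
  }
  if (max(c(labels$foreground, labels$background)) > graph$n_nodes)
    stop("label index outside image")
  sol <- solve_cmc(graph, labels, params, init)
  eff <- c(unclass(graph$config),
           list(lambda = params$lambda, r1 = sol$r1, r2 = sol$r2,
                relax = params$relax, cg_tol = params$cg_tol,
                cg_maxiter = params$cg_maxiter, outer_tol = params$outer_tol,
                residual_tol = params$residual_tol, max_outer = params$max_outer,
                threshold = params$threshold, init = init))
  structure(list(mask = sol$mask, membership = sol$u, labels = labels,
                 graph = graph, params = params, image = img,
                 iterations = sol$iterations, converged = sol$converged,
                 energy = utils::tail(sol$history$energy, 1),
                 history = sol$history, state = sol[c("v", "d", "mu1", "mu2", "mu3")],
                 provenance = eff),
            class = "patchcut")
}

#' Re-segment with new labels, reusing the cached graph
#'
#' Graph construction is the expensive image-modeling step; it depends only on
#' the image, so new scribbles can be segmented against the stored graph.
#'
#' @param object a fitted `patchcut` object.
#' @param labels new labels ([label_set] or label map matrix).
#' @param params optional new [solver_params].
#' @param ... unused.
#' @return a new `patchcut` fit.
#' @export
#' @method update patchcut
update.patchcut <- function(object, labels = NULL, params = NULL, ...) {
  patchcut(object$image,
           labels = if (is.null(labels)) object$labels else labels,
           graph = object$graph,
           params = if (is.null(params)) object$params else params)
}

#' @export
#' @method print patchcut
print.patchcut <- function(x, ...) {
  cat(sprintf("patchcut segmentation: %d x %d image\n",
              nrow(x$mask), ncol(x$mask)))
  cat(sprintf("  foreground: %d px (%.1f%%); labels: %d fg / %d bg\n",
              sum(x$mask), 100 * mean(x$mask),
              length(x$labels$foreground), length(x$labels$background)))
  cat(sprintf("  %d outer iterations (%s), final energy %.4g\n",
              x$iterations, if (x$converged) "converged" else "iteration cap",
              x$energy))
  invisible(x)
}

#' @export
#' @method summary patchcut
summary.patchcut <- function(object, ...) {
  h <- object$history
  structure(list(shape = dim(object$mask),
                 foreground_px = sum(object$mask),
                 foreground_frac = mean(object$mask),
                 iterations = object$iterations,
                 converged = object$converged,
                 energy = object$energy,
                 final_rel_change = utils::tail(h$rel_change, 1),
                 final_res_uv = utils::tail(h$res_uv, 1),
                 final_res_gd = utils::tail(h$res_gd, 1),
                 membership_range = range(object$membership),
                 provenance = object$provenance),
            class = "summary.patchcut")
}

#' @export
#' @method print summary.patchcut
print.summary.patchcut <- function(x, ...) {
  cat(sprintf("patchcut fit on %d x %d image\n", x$shape[1], x$shape[2]))
  cat(sprintf("  foreground: %d px (%.2f%%)\n", x$foreground_px,
              100 * x$foreground_frac))
  cat(sprintf("  iterations: %d (%s)\n", x$iterations,
              if (x$converged) "converged" else "hit max_outer"))
  cat(sprintf("  energy: %.6g\n", x$energy))
  cat(sprintf("  final rel. change %.2e, residuals |u-v| %.2e, |grad v-d| %.2e\n",
              x$final_rel_change, x$final_res_uv, x$final_res_gd))
  cat(sprintf("  membership range: [%.3g, %.3g]\n",
              x$membership_range[1], x$membership_range[2]))
  invisible(x)
}

#' @export
fitted.patchcut <- function(object, ...) object$membership

#' Predict a mask at a different binarization threshold
#'
#' @param object a `patchcut` fit.
#' @param threshold binarization threshold in (0,1); defaults to the fitted one.
#' @param type `"mask"` (0/1 matrix) or `"membership"` (the relaxed field).
#' @param ... unused.
#' @export
predict.patchcut <- function(object, threshold = NULL,
                             type = c("mask", "membership"), ...) {
  type <- match.arg(type)
  if (type == "membership") return(object$membership)
  if (is.null(threshold)) threshold <- object$provenance$threshold
  binarize(object$membership, threshold, object$labels)
}

#' Splitting residual history of a fit
#'
#' @param object a `patchcut` fit.
#' @param ... unused.
#' @return data.frame with per-outer-iteration `energy`, `rel_change`,
#'   `res_uv`, `res_gd`.
#' @export
residuals.patchcut <- function(object, ...) object$history

#' Plot a segmentation fit
#'
#' Shows the image with the segmentation contour and the scribbles, and
#' optionally the relaxed membership field.
#'
#' @param x a `patchcut` fit.
#' @param which `"mask"`, `"membership"`, or `"both"`.
#' @param ... passed to [graphics::image()].
#' @export
plot.patchcut <- function(x, which = c("mask", "membership", "both"), ...) {
  which <- match.arg(which)
  img <- as_intensity_matrix(x$image)
  nr <- nrow(img); nc <- ncol(img)
  show_panel <- function(bg, main) {
    graphics::image(t(bg)[, nr:1], col = grDevices::gray.colors(256),
                    axes = FALSE, main = main, useRaster = TRUE, ...)
    b <- boundary_pixels(x$mask)
    if (length(b)) {
      rc <- arrayInd(b, dim(x$mask))
      graphics::points((rc[, 2] - 0.5) / nc, 1 - (rc[, 1] - 0.5) / nr,
                       pch = ".", col = "red", cex = 2)
    }
    fg <- arrayInd(x$labels$foreground, dim(x$mask))
    graphics::points((fg[, 2] - 0.5) / nc, 1 - (fg[, 1] - 0.5) / nr,
                     pch = ".", col = "yellow", cex = 2)
    if (length(x$labels$background)) {
      bgp <- arrayInd(x$labels$background, dim(x$mask))
      graphics::points((bgp[, 2] - 0.5) / nc, 1 - (bgp[, 1] - 0.5) / nr,
                       pch = ".", col = "cyan", cex = 2)
    }
  }
  if (which == "both") {
    op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
    show_panel(img, "image + contour")
    show_panel(x$membership * 255, "membership + contour")
  } else if (which == "mask") {
    show_panel(img, "image + contour")
  } else {
    show_panel(x$membership * 255, "membership + contour")
  }
  invisible(x)
}

# indices of mask pixels 4-adjacent to the complement
boundary_pixels <- function(mask) {
  m <- mask != 0
  nr <- nrow(m); nc <- ncol(m)
  pad <- function(shift_r, shift_c) {
    out <- matrix(TRUE, nr, nc)
    rs <- seq_len(nr) + shift_r; cs <- seq_len(nc) + shift_c
    ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
    out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
    out
  }
  nb <- pad(1, 0) & pad(-1, 0) & pad(0, 1) & pad(0, -1)
  which(m & !nb)
}
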