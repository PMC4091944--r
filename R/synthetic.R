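#' Simulate a speckled ultrasound phantom
#'
#' Generates a piecewise-constant tissue map and corrupts it with
#' signal-dependent Gaussian speckle: `v = u0 + u0^exponent * sigma * n`
#' with `n` standard normal, so the local noise variance grows with the local
#' mean intensity (`Var(v) = u0 * sigma^2` at the default exponent 0.5), the
#' regime that fits log-compressed B-mode data.  Negative values are clipped
#' at zero.
#'
#' The speckle grain (cell size) is controlled by `smoothing`: the normal
#' field is Gaussian-filtered with that standard deviation and renormalized to
#' unit variance, so the pointwise variance law is preserved while the field
#' becomes spatially correlated.  Each tissue region receives its own
#' independent field (distinct scatterer populations decorrelate across a
#' tissue boundary).
#'
#' @param shape (rows, cols), default `c(128, 128)`.
#' @param geometry `"disk"`, `"ellipse"` or `"ring"`.
#' @param center (row, col) of the structure; defaults to the image center.
#' @param semi_axes (a, b) semi-axes in pixels (`a` along columns); a disk
#'   uses `semi_axes[1]` for both.
#' @param angle rotation of the ellipse in degrees.
#' @param ring_thickness band thickness in pixels for `"ring"`; the bright
#'   band lies just outside the ground-truth ellipse (a skull around the
#'   measured head outline).
#' @param fg_level,bg_level mean intensity of the structure (disk/ellipse
#'   interior, or ring band) and of the rest.
#' @param sigma_noise noise scale; a single value, or length 2 `(bg, fg)` for
#'   region-dependent speckle strength.
#' @param smoothing speckle grain: Gaussian blur standard deviation in pixels
#'   applied to the noise field (0 = white speckle).
#' @param exponent exponent of the intensity in the noise amplitude
#'   (0.5 = variance proportional to mean).
#' @param seed integer seed; the phantom is fully determined by it.
#' @param spacing_mm pixel spacing for the returned image.
#' @return list with `image` (a [us_image]) and `ground_truth` (logical
#'   matrix; for `"ring"` the region enclosed by the band).
#' @export
make_phantom <- function(shape = c(128, 128), geometry = c("disk", "ellipse", "ring"),
                         center = NULL, semi_axes = c(30, 30), angle = 0,
                         ring_thickness = 4,
                         fg_level = 140, bg_level = 60, sigma_noise = 1.5,
                         smoothing = 0, exponent = 0.5, seed = 0,
                         spacing_mm = c(1, 1)) {
  geometry <- match.arg(geometry)
  nr <- shape[1]; nc <- shape[2]
  if (is.null(center)) center <- (shape + 1) / 2
  stopifnot(all(sigma_noise >= 0), smoothing >= 0)
  if (length(sigma_noise) == 1L) sigma_noise <- rep(sigma_noise, 2L)

  rr <- matrix(seq_len(nr), nr, nc)
  ccm <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  th <- angle * pi / 180
  x <- ccm - center[2]; y <- -(rr - center[1])
  xr <- x * cos(th) + y * sin(th)
  yr <- -x * sin(th) + y * cos(th)
  a <- semi_axes[1]; b <- if (geometry == "disk") semi_axes[1] else semi_axes[2]
  q_in <- (xr / a)^2 + (yr / b)^2
  gt <- q_in <= 1
  if (geometry == "ring") {
    q_out <- (xr / (a + ring_thickness))^2 + (yr / (b + ring_thickness))^2
    bright <- !gt & q_out <= 1
  } else {
    bright <- gt
  }
  u0 <- ifelse(bright, fg_level, bg_level)
  sig <- ifelse(bright, sigma_noise[2], sigma_noise[1])

  v <- with_seed(as.integer(seed), {
    nz_bg <- matrix(stats::rnorm(nr * nc), nr, nc)
    nz_fg <- matrix(stats::rnorm(nr * nc), nr, nc)
    if (smoothing > 0) {
      nz_bg <- blur_unit_variance(nz_bg, smoothing)
      nz_fg <- blur_unit_variance(nz_fg, smoothing)
    }
    nz <- ifelse(bright, nz_fg, nz_bg)
    u0 + u0^exponent * sig * nz
  })
  v[v < 0] <- 0
  list(image = us_image(v, spacing_mm = spacing_mm), ground_truth = gt)
}

# Gaussian blur (separable, replicate boundary) renormalized so white noise
# keeps unit variance
blur_unit_variance <- function(m, s) {
  r <- max(1L, ceiling(3 * s))
  k <- exp(-((-r):r)^2 / (2 * s^2))
  k <- k / sum(k)
  conv1 <- function(v) {
    vp <- c(rep(v[1], r), v, rep(v[length(v)], r))
    as.numeric(stats::filter(vp, k, sides = 2))[(r + 1):(length(v) + r)]
  }
  out <- apply(m, 2, conv1)
  out <- t(apply(out, 1, conv1))
  out / sum(k^2)
}

#' The canonical disk phantom fixture
#'
#' 128 x 128 disk of radius 30 px (mean 140) on background 60, white speckle
#' `sigma_noise = 1.5`, seed 0; one foreground line scribble through the disk
#' and one background line outside it.
#'
#' @param seed noise seed (default 0, the canonical fixture).
#' @return list with `image`, `ground_truth`, `label_map`.
#' @export
default_phantom <- function(seed = 0) {
  ph <- make_phantom(seed = seed)
  lm <- label_map(c(128, 128))
  lm <- label_line(lm, c(64, 55), c(64, 75), code = 1L)
  lm <- label_line(lm, c(10, 20), c(10, 100), code = 2L)
  list(image = ph$image, ground_truth = ph$ground_truth, label_map = lm)
}

#' The canonical texture-only phantom fixture
#'
#' Equal mean intensity (300) inside and outside a radius-30 disk; the two
#' regions differ only in speckle: strong coarse speckle inside
#' (`sigma` 8, grain 10 px) against a nearly homogeneous background
#' (`sigma` 0.3).  The grain is comparable to the search window so that
#' same-tissue patches remain similar across the whole window; with fine
#' uncorrelated speckle the high-variance tissue is internally dissimilar at
#' window scale and no weight valley exists along the boundary.  Labels follow
#' the click-drag elliptic protocol: a filled inner ellipse (radius 18) and an
#' outer elliptic contour (radius 42).
#'
#' @param seed noise seed (default 0, the canonical fixture).
#' @return list with `image`, `ground_truth`, `label_map`.
#' @export
texture_phantom <- function(seed = 0) {
  ph <- make_phantom(fg_level = 300, bg_level = 300,
                     sigma_noise = c(0.3, 8), smoothing = 10, seed = seed)
  lm <- label_map(c(128, 128))
  lm <- label_ellipse(lm, c(64.5, 64.5), c(18, 18), code = 1L, filled = TRUE)
  lm <- label_ellipse(lm, c(64.5, 64.5), c(42, 42), code = 2L, filled = FALSE)
  list(image = ph$image, ground_truth = ph$ground_truth, label_map = lm)
}

#' A fetal-head-like ring phantom
#'
#' A bright elliptic band (skull) around a speckled interior; the ground
#' truth is the enclosed ellipse (the head outline that biometry measures).
#'
#' @param semi_axes head ellipse semi-axes in pixels.
#' @param angle head orientation in degrees.
#' @param seed noise seed.
#' @return list with `image`, `ground_truth`, `label_map`, and `hc_mm_true`,
#'   the circumference `pi * (a + b) * spacing` of the generating ellipse.
#' @export
head_phantom <- function(semi_axes = c(30, 20), angle = 0, seed = 0) {
  ph <- make_phantom(geometry = "ring", semi_axes = semi_axes, angle = angle,
                     ring_thickness = 4, fg_level = 200, bg_level = 80,
                     sigma_noise = 1.5, seed = seed)
  lm <- label_map(c(128, 128))
  lm <- label_ellipse(lm, c(64.5, 64.5), pmax(semi_axes / 2.5, 4), angle,
                      code = 1L, filled = TRUE)
  lm <- label_ellipse(lm, c(64.5, 64.5), semi_axes + 12, angle,
                      code = 2L, filled = FALSE)
  list(image = ph$image, ground_truth = ph$ground_truth, label_map = lm,
       hc_mm_true = pi * sum(semi_axes))
}
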