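#' Create an empty label map
#'
#' A label map is an integer matrix with codes 0 (unlabeled), 1 (foreground
#' scribble), 2 (background scribble).
#'
#' @param shape integer length-2 (rows, cols).
#' @return integer matrix of zeros.
#' @export
label_map <- function(shape) {
  matrix(0L, shape[1], shape[2])
}

.check_code <- function(code) {
  code <- as.integer(code)
  if (!code %in% c(1L, 2L)) stop("label code must be 1 (foreground) or 2 (background)")
  code
}

#' Rasterize a thick line scribble into a label map
#'
#' Marks every pixel whose center lies within `thickness/2` of the segment
#' `p0`--`p1`.  Existing labels of a different code are kept unless
#' `overwrite = TRUE`.
#'
#' @param map label map matrix (modified copy is returned).
#' @param p0,p1 integer (row, col) endpoints, inside the image.
#' @param code 1 (foreground) or 2 (background).
#' @param thickness line thickness in pixels (>= 1).
#' @param overwrite replace conflicting existing labels.
#' @return the updated label map.
#' @export
label_line <- function(map, p0, p1, code = 1L, thickness = 1, overwrite = FALSE) {
  code <- .check_code(code)
  nr <- nrow(map); nc <- ncol(map)
  if (any(c(p0, p1) < 1) || p0[1] > nr || p1[1] > nr || p0[2] > nc || p1[2] > nc)
    stop("line endpoints outside image")
  stopifnot(thickness >= 1)
  rr <- row(map); cc <- col(map)
  # distance from each pixel center to the segment
  vx <- p1[1] - p0[1]; vy <- p1[2] - p0[2]
  len2 <- vx^2 + vy^2
  if (len2 == 0) {
    d <- sqrt((rr - p0[1])^2 + (cc - p0[2])^2)
  } else {
    t <- ((rr - p0[1]) * vx + (cc - p0[2]) * vy) / len2
    t <- pmin(pmax(t, 0), 1)
    d <- sqrt((rr - (p0[1] + t * vx))^2 + (cc - (p0[2] + t * vy))^2)
  }
  sel <- d <= thickness / 2
  if (!overwrite) sel <- sel & (map == 0L | map == code)
  map[sel] <- code
  map
}

#' Rasterize an elliptic scribble into a label map
#'
#' Either the filled interior or a one-pixel contour band.  Clipped at the
#' image border.
#'
#' @param map label map matrix.
#' @param center (row, col) center.
#' @param semi_axes (a, b) semi-axis lengths in pixels, `a` along the rotated
#'   column direction.
#' @param angle rotation in degrees (counter-clockwise in (col, -row)
#'   physical coordinates).
#' @param code 1 or 2.
#' @param filled mark the interior (`TRUE`) or the contour band (`FALSE`).
#' @param overwrite replace conflicting existing labels.
#' @return the updated label map.
#' @export
label_ellipse <- function(map, center, semi_axes, angle = 0, code = 1L,
                          filled = TRUE, overwrite = FALSE) {
  code <- .check_code(code)
  stopifnot(all(semi_axes > 0))
  rr <- row(map); cc <- col(map)
  th <- angle * pi / 180
  # physical coords: x = col, y = -row (so positive angles are CCW on screen)
  x <- cc - center[2]; y <- -(rr - center[1])
  xr <- x * cos(th) + y * sin(th)
  yr <- -x * sin(th) + y * cos(th)
  q <- (xr / semi_axes[1])^2 + (yr / semi_axes[2])^2
  inside <- q <= 1
  sel <- if (filled) inside else inside & !erode4(inside)
  if (!overwrite) sel <- sel & (map == 0L | map == code)
  map[sel] <- code
  map
}

# 4-neighborhood erosion (border treated as outside)
erode4 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  sh <- function(dr, dc) {
    out <- matrix(FALSE, nr, nc)
    rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
    okr <- rs >= 1 & rs <= nr; okc <- cs >= 1 & cs <= nc
    out[okr, okc] <- m[rs[okr], cs[okc]]
    out
  }
  m & sh(1, 0) & sh(-1, 0) & sh(0, 1) & sh(0, -1)
}

#' Draw a deterministic pseudo-random freehand blob
#'
#' Emulates a freehand scribble: a star-shaped region whose radius is a
#' smoothed random function of the polar angle, seeded so that the same seed
#' always produces the same blob.  The blob is contained in `region`.
#'
#' @param map label map matrix.
#' @param seed integer seed.
#' @param region bounding box `c(r0, c0, r1, c1)` inside the image.
#' @param code 1 or 2.
#' @param overwrite replace conflicting existing labels.
#' @return the updated label map.
#' @export
label_blob <- function(map, seed, region, code = 1L, overwrite = FALSE) {
  code <- .check_code(code)
  r0 <- region[1]; c0 <- region[2]; r1 <- region[3]; c1 <- region[4]
  if (r0 < 1 || c0 < 1 || r1 > nrow(map) || c1 > ncol(map) || r0 > r1 || c0 > c1)
    stop("region outside image")
  cen <- c((r0 + r1) / 2, (c0 + c1) / 2)
  rmax <- min(r1 - r0, c1 - c0) / 2
  radii <- with_seed(as.integer(seed), {
    k <- 24L
    raw <- stats::runif(k, 0.45, 1)
    # circular moving-average smoothing for a smooth closed outline
    sm <- (raw + raw[c(2:k, 1)] + raw[c(k, 1:(k - 1))]) / 3
    sm * rmax
  })
  rr <- row(map); cc <- col(map)
  dy <- rr - cen[1]; dx <- cc - cen[2]
  ang <- atan2(dy, dx)  # (-pi, pi]
  k <- length(radii)
  idx <- floor((ang + pi) / (2 * pi) * k)
  frac <- (ang + pi) / (2 * pi) * k - idx
  i0 <- (idx %% k) + 1L; i1 <- ((idx + 1L) %% k) + 1L
  rad <- (1 - frac) * radii[i0] + frac * radii[i1]
  sel <- sqrt(dx^2 + dy^2) <= matrix(rad, nrow(map), ncol(map))
  sel[rr < r0 | rr > r1 | cc < c0 | cc > c1] <- FALSE
  if (!overwrite) sel <- sel & (map == 0L | map == code)
  map[sel] <- code
  map
}

# run code with a temporary RNG state, restoring the caller's stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Convert a label map to a [label_set]
#'
#' @param map integer matrix with codes in `{0, 1, 2}`.
#' @return a [label_set] of pixel indices.
#' @export
to_label_set <- function(map) {
  if (!all(map %in% c(0L, 1L, 2L))) stop("label map codes must be 0, 1 or 2")
  fg <- which(map == 1L)
  bg <- which(map == 2L)
  if (length(fg) == 0L) stop("label map has no foreground pixels")
  label_set(fg, bg)
}

#' Rasterize a [label_set] back to a label map
#'
#' @param labels a [label_set].
#' @param shape (rows, cols).
#' @return integer label map.
#' @export
from_label_set <- function(labels, shape) {
  m <- label_map(shape)
  m[labels$foreground] <- 1L
  m[labels$background] <- 2L
  m
}

#' Read / write a label map as a single-channel PNG
#'
#' Codes 0/1/2 are stored as gray levels 0, 127, 255 (palette documented so
#' files are viewable).  Conflicting or unknown codes are rejected at load.
#'
#' @param map integer label map.
#' @param path PNG path.
#' @return `read_label_map`: the label map matrix; `write_label_map`: the
#'   path, invisibly.
#' @export
write_label_map <- function(map, path) {
  if (!all(map %in% c(0L, 1L, 2L))) stop("label map codes must be 0, 1 or 2")
  png::writePNG(matrix(c(0, 127 / 255, 1)[map + 1L], nrow(map), ncol(map)), path)
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1]
  v <- round(a * 255)
  m <- matrix(NA_integer_, nrow(a), ncol(a))
  m[v == 0] <- 0L; m[v == 127] <- 1L; m[v == 255] <- 2L
  if (anyNA(m)) stop("corrupt label map: unknown codes present")
  m
}
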