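#' Axis of elongation of a binary mask
#'
#' Centroid and principal-axis orientation from central second-order moments:
#' `theta = 0.5 * atan2(2 mu11, mu20 - mu02)`, expressed in degrees in
#' (-90, 90].  Coordinates are (col = x, row = y with rows increasing
#' downward); theta is measured from the column axis, counter-clockwise in
#' physical (display) orientation.  A perfectly circular mask has theta 0 by
#' tie-break.
#'
#' @param mask binary matrix, nonempty.
#' @return list with `centroid` (row, col) and `theta` degrees.
#' @export
axis_of_elongation <- function(mask) {
  m <- as_intensity_matrix(mask) != 0
  idx <- which(m)
  if (length(idx) == 0L) stop("empty mask")
  rc <- arrayInd(idx, dim(m))
  rbar <- mean(rc[, 1]); cbar <- mean(rc[, 2])
  # physical y points up: y = -(row - rbar)
  x <- rc[, 2] - cbar; y <- -(rc[, 1] - rbar)
  mu20 <- mean(x^2); mu02 <- mean(y^2); mu11 <- mean(x * y)
  if (abs(mu11) < 1e-12 && abs(mu20 - mu02) < 1e-12) {
    theta <- 0
  } else {
    theta <- 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
  }
  if (theta <= -90) theta <- theta + 180
  if (theta > 90) theta <- theta - 180
  list(centroid = c(rbar, cbar), theta = theta)
}

# length of the mask chord through `centroid` along direction `theta_deg`,
# in mm; sampled at quarter-pixel steps from first to last covered sample
chord_length_mm <- function(mask, centroid, theta_deg, spacing_mm) {
  m <- as_intensity_matrix(mask) != 0
  nr <- nrow(m); nc <- ncol(m)
  th <- theta_deg * pi / 180
  # direction in (row, col) pixel coords; physical y up means row = -sin
  dr <- -sin(th); dc <- cos(th)
  tmax <- sqrt(nr^2 + nc^2)
  ts <- seq(-tmax, tmax, by = 0.25)
  rs <- round(centroid[1] + ts * dr)
  cs <- round(centroid[2] + ts * dc)
  ok <- rs >= 1 & rs <= nr & cs >= 1 & cs <= nc
  hit <- logical(length(ts))
  hit[ok] <- m[cbind(rs[ok], cs[ok])]
  if (!any(hit)) return(0)
  t0 <- ts[which(hit)[1]]; t1 <- ts[rev(which(hit))[1]]
  # half a sampling step beyond both covered ends
  span <- (t1 - t0) + 0.25
  sqrt((span * dr * spacing_mm[1])^2 + (span * dc * spacing_mm[2])^2)
}

#' Orthogonal diameters of a mask through its centroid
#'
#' The extent of the mask along the elongation axis (first diameter, the
#' occipito-frontal diameter for a fetal head) and along the perpendicular
#' direction through the same centroid (biparietal diameter), converted to
#' mm via the pixel spacing.
#'
#' @param mask binary matrix.
#' @param centroid,theta as returned by [axis_of_elongation()]; computed from
#'   the mask when omitted.
#' @param spacing_mm (row, col) pixel spacing in mm.
#' @return list with `ofd_mm` and `bpd_mm` (`ofd_mm >= bpd_mm` is not forced
#'   here; [head_biometry()] orders them).
#' @export
diameters <- function(mask, centroid = NULL, theta = NULL, spacing_mm = c(1, 1)) {
  if (is.null(centroid) || is.null(theta)) {
    ax <- axis_of_elongation(mask)
    centroid <- ax$centroid; theta <- ax$theta
  }
  list(ofd_mm = chord_length_mm(mask, centroid, theta, spacing_mm),
       bpd_mm = chord_length_mm(mask, centroid, theta + 90, spacing_mm))
}

#' Head circumference from the two diameters
#'
#' Ellipse-perimeter approximation `HC = coef * (OFD + BPD)` with the default
#' `coef = pi/2` (exact for a circle, the standard obstetric-chart convention
#' for an ellipse with axes OFD and BPD).  An alternate multiplier (e.g. 1.62)
#' can be supplied.
#'
#' @param ofd_mm,bpd_mm positive diameters in mm.
#' @param coef multiplier (default `pi/2`).
#' @return circumference in mm.
#' @export
head_circumference <- function(ofd_mm, bpd_mm, coef = pi / 2) {
  stopifnot(ofd_mm > 0, bpd_mm > 0, coef > 0)
  coef * (ofd_mm + bpd_mm)
}

#' Full fetal-head biometry of a binary segmentation
#'
#' Centroid and axis of elongation by second-order moments, occipito-frontal
#' and biparietal diameters as centroid-chord extents along and across that
#' axis, and head circumference from the ellipse-perimeter approximation.
#'
#' @param mask binary head mask (or a `patchcut` fit, whose mask is used).
#' @param spacing_mm (row, col) pixel spacing in mm; taken from the fitted
#'   image when a `patchcut` object is given.
#' @param hc_coef multiplier for [head_circumference()].
#' @return object of class `biometry_result`: `centroid`, `theta`, `ofd_mm`,
#'   `bpd_mm`, `hc_mm`.
#' @export
head_biometry <- function(mask, spacing_mm = c(1, 1), hc_coef = pi / 2) {
  if (inherits(mask, "patchcut")) {
    spacing_mm <- spacing_mm(mask$image)
    mask <- mask$mask
  }
  ax <- axis_of_elongation(mask)
  di <- diameters(mask, ax$centroid, ax$theta, spacing_mm)
  ofd <- max(di$ofd_mm, di$bpd_mm)
  bpd <- min(di$ofd_mm, di$bpd_mm)
  theta <- if (di$ofd_mm >= di$bpd_mm) ax$theta else ax$theta + 90
  if (theta > 90) theta <- theta - 180
  structure(list(centroid = ax$centroid, theta = theta,
                 ofd_mm = ofd, bpd_mm = bpd,
                 hc_mm = head_circumference(ofd, bpd, hc_coef)),
            class = "biometry_result")
}

#' @export
#' @method print biometry_result
print.biometry_result <- function(x, ...) {
  cat(sprintf("biometry: centroid (%.1f, %.1f), theta %.1f deg\n",
              x$centroid[1], x$centroid[2], x$theta))
  cat(sprintf("  OFD %.1f mm, BPD %.1f mm, HC %.1f mm\n",
              x$ofd_mm, x$bpd_mm, x$hc_mm))
  invisible(x)
}

#' Write biometry results as CSV
#'
#' @param results list of `biometry_result` objects.
#' @param path CSV path.
#' @param ... equal-length per-case annotation columns.
#' @return the data.frame written, invisibly.
#' @export
write_biometry_csv <- function(results, path, ...) {
  df <- do.call(rbind, lapply(results, function(r)
    data.frame(centroid_row = r$centroid[1], centroid_col = r$centroid[2],
               theta_deg = r$theta, ofd_mm = r$ofd_mm, bpd_mm = r$bpd_mm,
               hc_mm = r$hc_mm)))
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
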