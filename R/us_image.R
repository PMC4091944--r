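#' Construct a 2D ultrasound image
#'
#' Light container for a nonnegative grayscale intensity grid with physical
#' pixel spacing.  Intensities must be nonnegative because the patch distance
#' normalizes squared differences by local intensity.
#'
#' @param intensities numeric matrix (rows x cols) of nonnegative intensities.
#' @param spacing_mm numeric length-2 vector, physical size of one pixel in mm
#'   as (row spacing, column spacing).
#' @return An object of class `us_image`: the intensity matrix with a
#'   `spacing_mm` attribute.
#' @examples
#' img <- us_image(matrix(100, 8, 8), spacing_mm = c(0.2, 0.2))
#' dim(img)
#' @export
us_image <- function(intensities, spacing_mm = c(1, 1)) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  if (nrow(intensities) < 1L || ncol(intensities) < 1L)
    stop("image must have at least one row and one column")
  if (anyNA(intensities) || any(intensities < 0))
    stop("intensities must be finite and nonnegative")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 2L)
  if (length(spacing_mm) != 2L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("spacing_mm must be two positive numbers")
  structure(intensities, spacing_mm = spacing_mm, class = c("us_image", "matrix"))
}

#' @export
#' @method print us_image
print.us_image <- function(x, ...) {
  sp <- attr(x, "spacing_mm")
  cat(sprintf("us_image: %d x %d pixels, spacing %.3g x %.3g mm, range [%.3g, %.3g]\n",
              nrow(x), ncol(x), sp[1], sp[2], min(x), max(x)))
  invisible(x)
}

#' Pixel spacing of an image
#' @param x a [us_image].
#' @return numeric length-2 (row, col) spacing in mm.
#' @export
spacing_mm <- function(x) {
  sp <- attr(x, "spacing_mm")
  if (is.null(sp)) c(1, 1) else sp
}

as_intensity_matrix <- function(x) {
  m <- unclass(x)
  attr(m, "spacing_mm") <- NULL
  m
}

#' Read a grayscale PNG or TIFF as a [us_image]
#'
#' Intensities are linearly rescaled to the 0..255 real range (the scale on
#' which the default graph kernel bandwidth is calibrated).  Multi-channel
#' images are averaged to one channel.
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @param spacing_mm physical pixel spacing (row, col) in mm.
#' @param rescale if `TRUE` (default) rescale linearly to \[0, 255\].
#' @return a [us_image].
#' @export
read_us_image <- function(path, spacing_mm = c(1, 1), rescale = TRUE) {
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext))
  if (length(dim(a)) == 3L) a <- apply(a, c(1, 2), mean)
  if (rescale) {
    rng <- range(a)
    a <- if (rng[2] > rng[1]) (a - rng[1]) / (rng[2] - rng[1]) * 255 else a * 0
  }
  us_image(a, spacing_mm = spacing_mm)
}

#' Write an image or mask to PNG or TIFF
#'
#' Binary masks are written as 0/255 PNG; real-valued fields are written
#' rescaled to \[0,1\] (PNG) or as 32-bit float (TIFF).
#'
#' @param x matrix (binary mask, membership field, or image).
#' @param path output path ending in .png, .tif or .tiff.
#' @param binary write as 0/255 binary mask.
#' @return `path`, invisibly.
#' @export
write_us_image <- function(x, path, binary = FALSE) {
  m <- as_intensity_matrix(x)
  ext <- tolower(tools::file_ext(path))
  if (binary) {
    m <- matrix(as.numeric(m != 0), nrow(m), ncol(m))
  } else if (ext == "png") {
    rng <- range(m)
    m <- if (rng[2] > rng[1]) (m - rng[1]) / (rng[2] - rng[1]) else m * 0
  }
  switch(ext,
    png = png::writePNG(m, path),
    tif = ,
    tiff = tiff::writeTIFF(m, path, bits.per.sample = 32L,
                           reduce = FALSE),
    stop("unsupported image format: ", ext))
  invisible(path)
}
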