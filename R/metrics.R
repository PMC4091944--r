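#' Overlap between a segmentation and a reference mask
#'
#' Pixel-count decomposition and the two overlap scores used throughout:
#' Dice coefficient `DCM = 2 TP / (2 TP + FN + FP)` and area overlap
#' `AO = 100 * TP / (TP + FN + FP)` (Jaccard-style, in percent).
#' `AO/100 <= DCM` always.  Two empty masks count as perfect agreement
#' (DCM 1, AO 100).
#'
#' @param seg binary matrix (segmentation), nonzero = foreground.
#' @param gt binary matrix (reference), same shape.
#' @return list of class `overlap_report`: `tp`, `fn`, `fp`, `dcm`, `ao`.
#' @export
overlap <- function(seg, gt) {
  seg <- as_intensity_matrix(seg) != 0
  gt <- as_intensity_matrix(gt) != 0
  if (!all(dim(seg) == dim(gt))) stop("shape mismatch between seg and gt")
  tp <- sum(seg & gt)
  fn <- sum(!seg & gt)
  fp <- sum(seg & !gt)
  if (tp + fn + fp == 0L) {
    dcm <- 1; ao <- 100
  } else {
    dcm <- 2 * tp / (2 * tp + fn + fp)
    ao <- 100 * tp / (tp + fn + fp)
  }
  structure(list(tp = tp, fn = fn, fp = fp, dcm = dcm, ao = ao),
            class = "overlap_report")
}

#' @export
#' @method print overlap_report
print.overlap_report <- function(x, ...) {
  cat(sprintf("overlap: TP %d, FN %d, FP %d | DCM %.4f, AO %.2f%%\n",
              x$tp, x$fn, x$fp, x$dcm, x$ao))
  invisible(x)
}

#' Write overlap/segmentation reports as CSV
#'
#' One row per case; any extra per-case fields (iterations, energy, seed,
#' initialization style) can be supplied through `...` columns.
#'
#' @param reports list of `overlap_report` objects.
#' @param path CSV output path.
#' @param ... equal-length vectors of per-case annotations.
#' @return the data.frame written, invisibly.
#' @export
write_overlap_csv <- function(reports, path, ...) {
  df <- do.call(rbind, lapply(reports, function(r)
    data.frame(tp = r$tp, fn = r$fn, fp = r$fp, dcm = r$dcm, ao = r$ao)))
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
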