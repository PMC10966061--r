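#' Construct a binary significant/insignificant mask
#'
#' Label 1 marks significant (object/organ) pixels that must never be
#' touched; label 0 marks the insignificant background available for
#' embedding.
#'
#' @param labels Matrix of 0/1 values, same shape as its image.
#' @return An object of class `binary_mask` with field `labels`.
#' @export
binary_mask <- function(labels) {
  if (!is.matrix(labels)) stop("`labels` must be a matrix")
  storage.mode(labels) <- "double"
  if (anyNA(labels) || !all(labels %in% c(0, 1))) {
    stop("mask labels must be exactly 0 or 1")
  }
  structure(list(labels = labels), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %dx%d, %.1f%% significant\n",
              nrow(x$labels), ncol(x$labels), 100 * mean(x$labels)))
  invisible(x)
}

#' @export
dim.binary_mask <- function(x) dim(x$labels)

#' Deterministic threshold-based mask provider
#'
#' Stand-in for a trained segmentation model: pixels brighter than
#' `rel_threshold` times a robust intensity scale are candidate foreground;
#' a morphological opening removes speckle (in particular the faint texture
#' that embedding itself imprints on the background of a stego image, which
#' a trained segmenter also ignores), a closing fills holes, and connected
#' components smaller than `min_component_px` are dropped.
#'
#' The threshold is a fraction of the representable peak `R = 2^depth - 1`
#' rather than of the image's own min-max range. An absolute threshold is
#' what makes masks recomputed from a stego image agree exactly with the
#' cover's mask: the significant pixels themselves are never touched by
#' embedding, so an identical threshold value classifies them identically,
#' while the image's extrema (which embedding can move) never enter the
#' decision. What embedding texture pushes above the threshold in the
#' background is removed by the opening and the component-size filter.
#'
#' @param img A [medical_image()].
#' @param rel_threshold Threshold as a fraction of the peak `R`, in (0, 1).
#'   The default 0.3 sits well above background (and above the texture
#'   that embedding at any `beta >= 10` imprints on it) and well below
#'   organ-level intensities.
#' @param opening_radius Radius (pixels) of the opening kernel; 0 disables.
#' @param closing_radius Radius (pixels) of the closing kernel; 0 disables.
#' @param min_component_px Minimum connected-component area kept.
#' @return A [binary_mask()]. An all-background image yields an all-zero mask.
#' @export
threshold_mask <- function(img, rel_threshold = 0.3, opening_radius = 3L,
                           closing_radius = 5L, min_component_px = 256L) {
  stopifnot(inherits(img, "medical_image"))
  if (rel_threshold <= 0 || rel_threshold >= 1) stop("rel_threshold must be in (0,1)")
  px <- img$pixels
  peak <- peak_value(img)
  fg <- px > rel_threshold * peak
  if (all(fg)) return(binary_mask(matrix(1, nrow(px), ncol(px))))
  m <- EBImage::Image(fg * 1)
  if (opening_radius > 0 && any(fg)) {
    m <- EBImage::opening(m, EBImage::makeBrush(2L * opening_radius + 1L, "disc"))
  }
  if (closing_radius > 0 && any(m > 0)) {
    m <- EBImage::closing(m, EBImage::makeBrush(2L * closing_radius + 1L, "disc"))
  }
  lab <- EBImage::bwlabel(m)
  if (min_component_px > 0 && max(lab) > 0) {
    sizes <- tabulate(as.integer(lab[lab > 0]))
    keep <- which(sizes >= min_component_px)
    m <- matrix(as.numeric(lab %in% keep & lab > 0), nrow(px), ncol(px))
  } else {
    m <- matrix(as.numeric(m > 0), nrow(px), ncol(px))
  }
  binary_mask(m)
}

#' Import an externally produced mask image
#'
#' Adapter for segmentation masks produced outside the package (for example
#' by a trained neural segmenter): any grayscale image where nonzero means
#' significant.
#'
#' @param mask_image Path to a grayscale image (PNG or DICOM).
#' @param shape Expected `c(rows, cols)`; mismatch is an alignment error.
#' @return A [binary_mask()].
#' @export
external_mask_adapter <- function(mask_image, shape) {
  img <- read_image(mask_image)
  if (!identical(as.integer(dim(img$pixels)), as.integer(shape))) {
    stop(sprintf("alignment error: mask is %dx%d, expected %dx%d",
                 nrow(img$pixels), ncol(img$pixels), shape[1], shape[2]))
  }
  binary_mask((img$pixels != 0) * 1)
}

#' Export a mask as an 8-bit style PNG (0/255 in a 16-bit container)
#'
#' @param mask A [binary_mask()].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  png::writePNG(mask$labels, path)
  invisible(path)
}

#' Intersection over union of two masks
#'
#' `|a AND b| / |a OR b|`. Two empty masks agree that nothing is
#' significant, so their IoU is defined as 1.
#'
#' @param a,b [binary_mask()] objects of the same shape.
#' @return IoU in `[0, 1]`.
#' @export
compute_iou <- function(a, b) {
  stopifnot(inherits(a, "binary_mask"), inherits(b, "binary_mask"))
  if (!identical(dim(a$labels), dim(b$labels))) {
    stop("alignment error: mask shapes differ")
  }
  inter <- sum(a$labels * b$labels)
  union <- sum((a$labels + b$labels) > 0)
  if (union == 0) return(1)
  inter / union
}

#' Normalized cross-correlation of two arrays
#'
#' Pearson-style correlation over all pixels,
#' `sum((a - mean(a)) (b - mean(b))) / (sd_a sd_b)`, in `[-1, 1]`. A value
#' near 1 means the two arrays agree up to a positive affine rescaling.
#'
#' @param a,b Numeric matrices (or `binary_mask` objects) of the same shape;
#'   neither may be constant.
#' @return NCC in `[-1, 1]`.
#' @export
compute_ncc <- function(a, b) {
  if (inherits(a, "binary_mask")) a <- a$labels
  if (inherits(b, "binary_mask")) b <- b$labels
  if (!identical(dim(a), dim(b))) stop("alignment error: shapes differ")
  da <- a - mean(a); db <- b - mean(b)
  na <- sqrt(sum(da^2)); nb <- sqrt(sum(db^2))
  if (na == 0 || nb == 0) stop("degenerate variance: constant input to NCC")
  sum(da * db) / (na * nb)
}
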