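#' Construct a medical image
#'
#' A `medical_image` is an integer-valued 2D frame together with its stored
#' bit depth and modality. It is the common currency of the package: covers,
#' stego images and attacked images are all `medical_image` objects.
#'
#' @param pixels Integer-valued matrix (rows x cols) of non-negative pixel
#'   values. Must be at least 8x8 and every value must fit in `bit_depth`
#'   bits.
#' @param bit_depth Stored bit depth, 12 or 16.
#' @param modality One of `"CT"`, `"MR"`, `"OTHER"`.
#' @param source_path Optional path the image was read from.
#' @return An object of class `medical_image` with fields `pixels`,
#'   `bit_depth`, `modality`, `source_path`.
#' @export
medical_image <- function(pixels, bit_depth = 16L, modality = c("OTHER", "CT", "MR"),
                          source_path = NULL) {
  modality <- match.arg(modality)
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  if (nrow(pixels) < 8L || ncol(pixels) < 8L) {
    stop("`pixels` must be at least 8x8")
  }
  if (!bit_depth %in% c(12L, 16L)) stop("`bit_depth` must be 12 or 16")
  storage.mode(pixels) <- "double"  # 16-bit values can exceed .Machine$integer range after arithmetic
  if (anyNA(pixels)) stop("`pixels` must not contain NA")
  if (any(pixels != floor(pixels))) stop("`pixels` must be integer-valued")
  rng <- range(pixels)
  if (rng[1] < 0 || rng[2] > 2^bit_depth - 1) {
    stop(sprintf("pixel values must lie in [0, %d] for bit depth %d",
                 2^bit_depth - 1, bit_depth))
  }
  structure(
    list(pixels = pixels, bit_depth = as.integer(bit_depth),
         modality = modality, source_path = source_path),
    class = "medical_image"
  )
}

#' @export
print.medical_image <- function(x, ...) {
  cat(sprintf("<medical_image> %dx%d, %d-bit, modality %s, range [%d, %d]\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth, x$modality,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.medical_image <- function(x) dim(x$pixels)

#' Peak value representable at an image's bit depth
#'
#' The maximum fluctuation R of the stored data type, `2^bit_depth - 1`;
#' used as the reference peak in PSNR.
#'
#' @param img A `medical_image` or a bit depth.
#' @return Integer peak value (4095 or 65535).
#' @export
peak_value <- function(img) {
  depth <- if (inherits(img, "medical_image")) img$bit_depth else as.integer(img)
  2^depth - 1
}

#' Read a medical image from DICOM or PNG
#'
#' DICOM input must be single-frame monochrome with unsigned integer pixels
#' (explicit VR little endian); the bit depth is taken from Bits Stored.
#' Grayscale PNG is accepted as a fixture-friendly fallback and is treated
#' as 16-bit.
#'
#' @param path Path to a `.dcm` or `.png` file.
#' @param modality Modality label to attach when the file does not carry one.
#' @return A [medical_image()].
#' @export
read_image <- function(path, modality = "OTHER") {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("dcm", "dicom", "")) {
    d <- dicom_read_minimal(path)
    mod <- if (d$modality %in% c("CT", "MR")) d$modality else modality
    medical_image(d$pixels, bit_depth = d$bit_depth, modality = mod,
                  source_path = path)
  } else if (ext == "png") {
    a <- png::readPNG(path)
    if (length(dim(a)) > 2L) {
      if (dim(a)[3] > 1L) stop("unsupported format: color PNG")
      a <- a[, , 1L]
    }
    # readPNG returns [0,1] with x/65535 resolution for 16-bit samples
    px <- round(a * 65535)
    medical_image(px, bit_depth = 16L, modality = modality, source_path = path)
  } else {
    stop("unsupported format: ", ext)
  }
}

#' Write a medical image as DICOM or PNG
#'
#' Output round-trips through [read_image()] to a pixel-identical image.
#' DICOM output preserves the stored bit depth; PNG output is 16-bit
#' grayscale.
#'
#' @param img A [medical_image()].
#' @param path Output path.
#' @param format `"auto"` (from extension), `"dicom"` or `"png"`.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, format = c("auto", "dicom", "png")) {
  stopifnot(inherits(img, "medical_image"))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "png") "png" else "dicom"
  }
  if (max(img$pixels) > peak_value(img)) {
    stop("pixel value exceeds bit depth range")
  }
  if (format == "dicom") {
    dicom_write_minimal(img$pixels, path, bit_depth = img$bit_depth,
                        modality = img$modality)
  } else {
    if (img$bit_depth != 16L) {
      stop("PNG output is 16-bit; write ", img$bit_depth, "-bit data as DICOM")
    }
    png_write_gray16(img$pixels, path)
  }
  invisible(path)
}

#' Min-max normalize an image to [0, 1]
#'
#' Affine map sending the image minimum to 0 and maximum to 1:
#' `(Img - min(Img)) / (max(Img) - min(Img))`. The source extrema are kept
#' on the result so the map can be inverted exactly.
#'
#' @param img A [medical_image()] with at least two distinct pixel values.
#' @return A `normalized_image`: list with `values` (real matrix in `[0,1]`),
#'   `norm_min`, `norm_max`, `bit_depth`, `modality`.
#' @export
normalize_image <- function(img) {
  stopifnot(inherits(img, "medical_image"))
  mn <- min(img$pixels); mx <- max(img$pixels)
  if (mx <= mn) stop("degenerate range: constant image cannot be normalized")
  v <- (img$pixels - mn) / (mx - mn)
  structure(
    list(values = v, norm_min = mn, norm_max = mx,
         bit_depth = img$bit_depth, modality = img$modality),
    class = "normalized_image"
  )
}

#' Invert min-max normalization back to integer pixels
#'
#' Applies the inverse affine map using the stored extrema, rounds
#' half-away-from-zero (fixed so stego files are bit-reproducible across
#' platforms) and clamps to the representable range. Exact inverse of
#' [normalize_image()] on integer images; clamping absorbs the small
#' out-of-range reals produced by embedding.
#'
#' @param nimg A `normalized_image`.
#' @param bit_depth Target bit depth (defaults to the source's).
#' @return A [medical_image()].
#' @export
denormalize_image <- function(nimg, bit_depth = nimg$bit_depth) {
  stopifnot(inherits(nimg, "normalized_image"))
  v <- nimg$values * (nimg$norm_max - nimg$norm_min) + nimg$norm_min
  px <- round_half_away(v)
  px[px < 0] <- 0
  lim <- 2^bit_depth - 1
  px[px > lim] <- lim
  medical_image(px, bit_depth = bit_depth, modality = nimg$modality)
}

# round half away from zero (round() in R rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
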