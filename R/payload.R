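#' Construct a QR bitmap
#'
#' @param bits 0/1 matrix, each QR module rendered as a `module_scale` x
#'   `module_scale` block of pixels.
#' @param module_scale Pixels per module (>= 1).
#' @return A `qr_bitmap` object.
#' @export
qr_bitmap <- function(bits, module_scale = 1L) {
  if (!is.matrix(bits)) stop("`bits` must be a matrix")
  storage.mode(bits) <- "double"
  if (anyNA(bits) || !all(bits %in% c(0, 1))) stop("QR bits must be 0 or 1")
  if (module_scale < 1L) stop("module_scale must be >= 1")
  structure(list(bits = bits, module_scale = as.integer(module_scale)),
            class = "qr_bitmap")
}

#' @export
dim.qr_bitmap <- function(x) dim(x$bits)

#' Render patient text as a QR bitmap
#'
#' Byte-mode QR symbol (versions 1-10), error-correction level M by
#' default, rendered at `module_scale` pixels per module. Bit 1 is a dark
#' module. [qr_to_text()] inverts it.
#'
#' @param text Non-empty UTF-8 string within QR capacity.
#' @param module_scale Pixels per module; 4 aligns modules with the 4x4
#'   embedding tiles, which lets module-level majority voting absorb
#'   isolated bit errors.
#' @param ec_level `"L"`, `"M"`, `"Q"` or `"H"`.
#' @param version QR version 1-10, or `NULL` to pick the smallest that fits.
#' @return A [qr_bitmap()].
#' @export
text_to_qr <- function(text, module_scale = 4L, ec_level = "M", version = NULL) {
  if (!nzchar(text)) stop("capacity error: empty payload")
  m <- qr_encode_matrix(text, level = ec_level, version = version)
  s <- as.integer(module_scale)
  bits <- m[rep(seq_len(nrow(m)), each = s), rep(seq_len(ncol(m)), each = s)]
  qr_bitmap(bits, module_scale = s)
}

#' Decode a QR bitmap back to text
#'
#' The bitmap is reduced to its module grid by majority vote over each
#' `module_scale` x `module_scale` cell (so isolated pixel errors inside a
#' module are absorbed), then decoded; module errors up to the
#' Reed-Solomon budget of the symbol's EC level are corrected.
#'
#' @param qr A [qr_bitmap()].
#' @return The decoded UTF-8 string; an undecodable bitmap is a decode
#'   error (signalling corrupted extraction).
#' @export
qr_to_text <- function(qr) {
  stopifnot(inherits(qr, "qr_bitmap"))
  s <- qr$module_scale
  b <- qr$bits
  if (any(dim(b) %% s != 0L)) stop("decode error: bitmap not a multiple of module_scale")
  nm <- nrow(b) %/% s
  if (s > 1L) {
    a <- array(b, c(s, nm, s, ncol(b) %/% s))
    counts <- apply(a, c(2L, 4L), sum)
    m <- (counts * 2 > s * s) * 1L  # ties (impossible for odd s*s... s^2 even: tie -> 0)
  } else {
    m <- b
  }
  qr_decode_matrix(m)
}

#' Map QR bits to embeddable message levels
#'
#' Message adjustment: bit 1 becomes `1 - alpha`, bit 0 becomes `alpha`
#' (default `alpha = 0.02`), keeping embedded values strictly inside the
#' quantization cells. Min-max normalization of a 0/1 bitmap is the
#' identity, so the bitmap enters this map unchanged.
#'
#' @param qr A [qr_bitmap()].
#' @param alpha Level offset in (0, 0.5).
#' @return An `adjusted_message`: list with `values` (matrix of `alpha` /
#'   `1 - alpha`), `alpha`, `module_scale`.
#' @export
adjust_message <- function(qr, alpha = 0.02) {
  stopifnot(inherits(qr, "qr_bitmap"))
  if (alpha <= 0 || alpha >= 0.5) stop("parameter error: alpha must be in (0, 0.5)")
  structure(list(values = ifelse(qr$bits >= 1, 1 - alpha, alpha),
                 alpha = alpha, module_scale = qr$module_scale),
            class = "adjusted_message")
}

#' Split an adjusted message into 4x4 blocks
#'
#' Pads to multiples of 4 with the bit-0 level (`alpha`, staying
#' in-protocol), then tiles row-major. The original shape is retained so
#' [unblockify_and_decide()] can strip the padding.
#'
#' @param msg An `adjusted_message` (or plain numeric matrix for recovered
#'   values).
#' @return A `message_blocks`: list with `blocks` (list of 4x4 matrices,
#'   row-major tile order), `original_shape`, `alpha`, `module_scale`.
#' @export
blockify_message <- function(msg) {
  if (inherits(msg, "adjusted_message")) {
    v <- msg$values; alpha <- msg$alpha; ms <- msg$module_scale
  } else {
    v <- msg; alpha <- NA_real_; ms <- 1L
  }
  orig <- dim(v)
  pr <- (4L - orig[1] %% 4L) %% 4L
  pc <- (4L - orig[2] %% 4L) %% 4L
  pad_val <- if (is.na(alpha)) 0 else alpha
  if (pr > 0L) v <- rbind(v, matrix(pad_val, pr, ncol(v)))
  if (pc > 0L) v <- cbind(v, matrix(pad_val, nrow(v), pc))
  tr <- nrow(v) %/% 4L; tc <- ncol(v) %/% 4L
  blocks <- vector("list", tr * tc)
  idx <- 1L
  for (i in seq_len(tr)) {
    for (j in seq_len(tc)) {
      blocks[[idx]] <- v[(4L * i - 3L):(4L * i), (4L * j - 3L):(4L * j)]
      idx <- idx + 1L
    }
  }
  structure(list(blocks = blocks, original_shape = as.integer(orig),
                 alpha = alpha, module_scale = ms),
            class = "message_blocks")
}

#' Reassemble recovered blocks and decide bits
#'
#' Inverse of [blockify_message()]: tiles are laid back row-major, padding
#' is stripped, and each recovered real value is decided as bit 1 iff it is
#' at least 0.5 (the maximum-margin rule for levels `alpha` / `1 - alpha`;
#' the tie at exactly 0.5 goes to 1).
#'
#' @param blocks A `message_blocks`.
#' @param module_scale Module scale to stamp on the result (defaults to the
#'   value carried by `blocks`).
#' @return A [qr_bitmap()].
#' @export
unblockify_and_decide <- function(blocks, module_scale = blocks$module_scale) {
  stopifnot(inherits(blocks, "message_blocks"))
  orig <- blocks$original_shape
  tr <- ceiling(orig[1] / 4L); tc <- ceiling(orig[2] / 4L)
  if (length(blocks$blocks) != tr * tc) {
    stop(sprintf("alignment error: %d blocks inconsistent with shape %dx%d",
                 length(blocks$blocks), orig[1], orig[2]))
  }
  v <- matrix(0, 4L * tr, 4L * tc)
  idx <- 1L
  for (i in seq_len(tr)) {
    for (j in seq_len(tc)) {
      v[(4L * i - 3L):(4L * i), (4L * j - 3L):(4L * j)] <- blocks$blocks[[idx]]
      idx <- idx + 1L
    }
  }
  v <- v[seq_len(orig[1]), seq_len(orig[2]), drop = FALSE]
  qr_bitmap((v >= 0.5) * 1, module_scale = module_scale)
}
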