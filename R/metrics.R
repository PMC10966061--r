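#' Mean squared error between two images
#'
#' `sum((I1 - I2)^2) / (M N)` in integer pixel units.
#'
#' @param a,b [medical_image()] objects of the same shape.
#' @return Non-negative real.
#' @export
compute_mse <- function(a, b) {
  stopifnot(inherits(a, "medical_image"), inherits(b, "medical_image"))
  if (!identical(dim(a$pixels), dim(b$pixels))) {
    stop("alignment error: image shapes differ")
  }
  mean((a$pixels - b$pixels)^2)
}

#' Peak signal-to-noise ratio in dB
#'
#' `10 log10(R^2 / MSE)` with `R = 2^bit_depth - 1` the maximum
#' fluctuation of the stored data type; `Inf` when the images are
#' identical.
#'
#' @param a,b [medical_image()] objects of the same shape and bit depth.
#' @return PSNR in dB (possibly `Inf`).
#' @export
compute_psnr <- function(a, b) {
  stopifnot(inherits(a, "medical_image"), inherits(b, "medical_image"))
  if (a$bit_depth != b$bit_depth) {
    stop("alignment error: bit depths differ (PSNR peak undefined)")
  }
  mse <- compute_mse(a, b)
  if (mse == 0) return(Inf)
  R <- peak_value(a)
  10 * log10(R^2 / mse)
}

#' Specify a noise attack
#'
#' @param kind `"gaussian"` (additive N(0, sigma^2)), `"uniform"` (additive
#'   U(-half_width, half_width)) or `"salt_pepper"` (a `density` fraction
#'   of pixels forced to 0 or the bit-depth maximum with equal
#'   probability). Amplitudes are in integer pixel units.
#' @param sigma,half_width,density Strength parameter of the respective
#'   kind; the defaults follow the package's evaluation settings
#'   (`0.005 R` additive noise, 1% salt-and-pepper).
#' @param seed Integer seed; attacks are reproducible.
#' @return An `attack_spec`.
#' @export
attack_spec <- function(kind = c("gaussian", "uniform", "salt_pepper"),
                        sigma = NULL, half_width = NULL, density = NULL,
                        seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "gaussian") {
    if (is.null(sigma)) sigma <- 0.005 * 65535
    if (sigma < 0) stop("sigma must be >= 0")
  } else if (kind == "uniform") {
    if (is.null(half_width)) half_width <- 0.005 * 65535
    if (half_width < 0) stop("half_width must be >= 0")
  } else {
    if (is.null(density)) density <- 0.01
    if (density < 0 || density > 1) stop("density must be in [0, 1]")
  }
  structure(list(kind = kind, sigma = sigma, half_width = half_width,
                 density = density, seed = as.integer(seed)),
            class = "attack_spec")
}

#' Apply a seeded noise attack to an image
#'
#' Additive noise is rounded and clamped to the representable range; a
#' zero-strength attack is the identity.
#'
#' @param img A [medical_image()].
#' @param spec An [attack_spec()].
#' @return The attacked [medical_image()].
#' @export
apply_attack <- function(img, spec) {
  stopifnot(inherits(img, "medical_image"), inherits(spec, "attack_spec"))
  px <- img$pixels
  R <- peak_value(img)
  px <- with_seed(spec$seed, {
    if (spec$kind == "gaussian") {
      if (spec$sigma > 0) px <- px + matrix(stats::rnorm(length(px), 0, spec$sigma), nrow(px))
      px
    } else if (spec$kind == "uniform") {
      if (spec$half_width > 0) {
        px <- px + matrix(stats::runif(length(px), -spec$half_width, spec$half_width), nrow(px))
      }
      px
    } else {
      n_hit <- round(spec$density * length(px))
      if (n_hit > 0) {
        pos <- sample.int(length(px), n_hit)
        px[pos] <- ifelse(stats::runif(n_hit) < 0.5, 0, R)
      }
      px
    }
  })
  px <- round_half_away(px)
  px[px < 0] <- 0
  px[px > R] <- R
  medical_image(px, bit_depth = img$bit_depth, modality = img$modality)
}

#' One embed-attack-extract robustness trial
#'
#' Embeds `message` into `cover`, attacks the stego image, re-derives the
#' mask from the attacked stego (the extraction-side protocol), extracts,
#' and reports the continuous message correlation, the attacked image's
#' PSNR against the cover, the fraction of correctly decided bits, and
#' whether the QR payload still decodes.
#'
#' @param cover A [medical_image()].
#' @param mask Cover-side [binary_mask()].
#' @param message An `adjusted_message` from [adjust_message()].
#' @param key An [embedding_key()].
#' @param spec An [attack_spec()].
#' @param mask_provider Function `medical_image -> binary_mask` used on the
#'   attacked stego; defaults to [threshold_mask()] defaults.
#' @return List with `ncc_message`, `psnr_db`, `bit_accuracy`, `decoded`.
#' @export
robustness_trial <- function(cover, mask, message, key = embedding_key(),
                             spec = attack_spec(), mask_provider = threshold_mask) {
  stopifnot(inherits(message, "adjusted_message"))
  blocks <- blockify_message(message)
  res <- embed_payload(cover, mask, blocks, key, verify = FALSE)
  attacked <- apply_attack(res$stego, spec)
  stego_mask <- mask_provider(attacked)
  key$message_shape <- blocks$original_shape
  rec <- extract_payload(attacked, stego_mask, key,
                         manifest_norm = c(res$manifest$norm_min, res$manifest$norm_max),
                         module_scale = message$module_scale)
  rec_vals <- unblockify_values(rec)
  ncc_msg <- compute_ncc(message$values, rec_vals)
  psnr <- if (attacked$bit_depth == cover$bit_depth) {
    compute_psnr(cover, attacked)
  } else {
    NA_real_
  }
  want_bits <- (message$values >= 0.5) * 1
  got <- unblockify_and_decide(rec, module_scale = message$module_scale)
  bit_acc <- mean(want_bits == got$bits)
  decoded <- tryCatch({
    qr_to_text(got)
    TRUE
  }, error = function(e) FALSE)
  list(ncc_message = ncc_msg, psnr_db = psnr, bit_accuracy = bit_acc,
       decoded = decoded)
}

# reassemble recovered real values (no bit decision), padding stripped
unblockify_values <- function(blocks) {
  orig <- blocks$original_shape
  tr <- ceiling(orig[1] / 4L); tc <- ceiling(orig[2] / 4L)
  v <- matrix(0, 4L * tr, 4L * tc)
  idx <- 1L
  for (i in seq_len(tr)) {
    for (j in seq_len(tc)) {
      v[(4L * i - 3L):(4L * i), (4L * j - 3L):(4L * j)] <- blocks$blocks[[idx]]
      idx <- idx + 1L
    }
  }
  v[seq_len(orig[1]), seq_len(orig[2]), drop = FALSE]
}
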