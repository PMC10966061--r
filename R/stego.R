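# Orthonormal type-II DCT basis. With orthonormal scaling, a 4x4 block of
# pixels in [0, 1] has every coefficient magnitude <= 4 (the DC of an
# all-ones block is exactly 4), which is the reading under which beta
# partitions the coefficient magnitude range [0, 4].
dct_matrix <- function(n = 4L) {
  u <- 0:(n - 1L)
  C <- outer(u, u, function(u, m) cos((2 * m + 1) * u * pi / (2 * n)))
  C <- C * sqrt(2 / n)
  C[1, ] <- sqrt(1 / n)
  C
}

.dct4 <- dct_matrix(4L)
# operator on vectorized 4x4 blocks: vec(C B C^T) = (C (x) C) vec(B)
.dct16 <- kronecker(.dct4, .dct4)

#' Orthonormal 2D type-II DCT of a 4x4 block
#'
#' `C(u,v) = a(u) a(v) sum_m sum_n I(m,n) cos((2m+1)u pi / 2M)
#' cos((2n+1)v pi / 2N)` with orthonormal scaling
#' (`a(0) = sqrt(1/N)`, `a(u>0) = sqrt(2/N)`).
#'
#' @param block 4x4 numeric matrix.
#' @return 4x4 coefficient matrix.
#' @export
dct2 <- function(block) {
  stopifnot(is.matrix(block), all(dim(block) == 4L))
  .dct4 %*% block %*% t(.dct4)
}

#' Inverse orthonormal 2D DCT of a 4x4 coefficient block
#'
#' Exact inverse of [dct2()].
#'
#' @param coeffs 4x4 coefficient matrix.
#' @return 4x4 pixel-domain matrix.
#' @export
idct2 <- function(coeffs) {
  stopifnot(is.matrix(coeffs), all(dim(coeffs) == 4L))
  t(.dct4) %*% coeffs %*% .dct4
}

#' Construct an embedding key
#'
#' The key holds everything extraction needs besides the stego image and
#' its mask: the interval count `beta`, the message level offset `alpha`,
#' the (unpadded) message shape, and an optional seed for a secret
#' permutation of the tile order.
#'
#' @param beta Number of quantization intervals partitioning the
#'   coefficient magnitude range `[0, 4]`; integer >= 2. Larger `beta`
#'   means smaller perturbations and higher stego fidelity.
#' @param alpha Message level offset in (0, 0.5).
#' @param message_shape `c(rows, cols)` of the message bitmap before
#'   padding.
#' @param tile_order_seed Optional integer; when set, the planned tiles are
#'   deterministically permuted so tile order itself is key material.
#' @return An `embedding_key`.
#' @export
embedding_key <- function(beta = 1000L, alpha = 0.02, message_shape = NULL,
                          tile_order_seed = NULL) {
  if (any(beta < 2)) stop("parameter error: beta must be >= 2")
  if (alpha <= 0 || alpha >= 0.5) stop("parameter error: alpha must be in (0, 0.5)")
  structure(list(beta = as.integer(beta), alpha = alpha,
                 message_shape = if (is.null(message_shape)) NULL else as.integer(message_shape),
                 tile_order_seed = tile_order_seed),
            class = "embedding_key")
}

#' Enumerate embeddable 4x4 tiles of the insignificant region
#'
#' All 4-aligned 4x4 tiles whose 16 pixels are all background (mask 0), in
#' row-major order over tiles; a `tile_order_seed` on the key applies a
#' seeded deterministic permutation. Identical inputs always give identical
#' plans.
#'
#' A guard ring keeps planned tiles at least `guard_radius` pixels away
#' from any significant pixel: embedding never writes next to the organ
#' boundary, so small boundary jitter in a recomputed mask cannot change
#' the plan (tile order is what synchronizes embedder and extractor).
#'
#' @param mask A [binary_mask()].
#' @param key Optional [embedding_key()] (for `tile_order_seed`).
#' @param guard_radius Exclusion margin, in pixels, around the significant
#'   region.
#' @return A `tile_plan`: list with `tile_origins` (matrix of 1-based
#'   `(row, col)` origins) and `image_shape`.
#' @export
plan_tiles <- function(mask, key = NULL, guard_radius = 8L) {
  stopifnot(inherits(mask, "binary_mask"))
  lab <- mask$labels
  if (guard_radius > 0 && any(lab > 0) && !all(lab > 0)) {
    lab <- EBImage::imageData(EBImage::dilate(
      EBImage::Image(lab), EBImage::makeBrush(2L * as.integer(guard_radius) + 1L, "disc")))
  }
  nr <- nrow(lab); nc <- ncol(lab)
  tr <- nr %/% 4L; tc <- nc %/% 4L
  lab4 <- lab[seq_len(4L * tr), seq_len(4L * tc), drop = FALSE]
  a <- array(lab4, c(4L, tr, 4L, tc))
  tile_sum <- apply(a, c(2L, 4L), sum)
  free <- which(t(tile_sum) == 0)  # transpose -> row-major enumeration
  if (length(free) == 0L) {
    origins <- matrix(integer(0), 0L, 2L)
  } else {
    ti <- (free - 1L) %/% tc + 1L   # tile row
    tj <- (free - 1L) %% tc + 1L    # tile col
    origins <- cbind(4L * (ti - 1L) + 1L, 4L * (tj - 1L) + 1L)
  }
  if (!is.null(key) && !is.null(key$tile_order_seed) && nrow(origins) > 1L) {
    perm <- with_seed(key$tile_order_seed, sample.int(nrow(origins)))
    origins <- origins[perm, , drop = FALSE]
  }
  colnames(origins) <- c("row", "col")
  structure(list(tile_origins = origins, image_shape = c(nr, nc)),
            class = "tile_plan")
}

#' Quantization embedding of one message value into one coefficient
#'
#' The coefficient magnitude's quantization cell `k` (of width `4/beta`) is
#' kept, and the within-cell position is replaced by the message value:
#' `out = sign(c) * (4k/beta + (4/beta) * m)` with
#' `k = min(floor(|c| beta / 4), beta - 1)`. The output magnitude stays
#' strictly inside cell `k`, so the perturbation is below `4/beta`.
#' Vectorized over coefficients.
#'
#' @param cover_coeff Coefficient(s), `|cover_coeff| <= 4`.
#' @param message_value Message level(s) in `{alpha, 1 - alpha}`.
#' @param beta Integer >= 2.
#' @return Stego coefficient(s).
#' @export
qun <- function(cover_coeff, message_value, beta) {
  if (any(beta < 2)) stop("parameter error: beta must be >= 2")
  if (any(message_value <= 0) || any(message_value >= 1)) {
    stop("parameter error: message values must lie strictly inside (0, 1)")
  }
  k <- pmin(floor(abs(cover_coeff) * beta / 4), beta - 1)
  s <- ifelse(cover_coeff < 0, -1, 1)
  s * (4 * k + 4 * message_value) / beta
}

#' Inverse quantization: recover the message value from a coefficient
#'
#' `k = min(floor(|c| beta / 4), beta - 1)`; returns
#' `(|c| - 4k/beta) * beta / 4`, the within-cell position, in `[0, 1)`.
#' Exact left inverse of [qun()]. Vectorized.
#'
#' @param stego_coeff Coefficient(s).
#' @param beta Integer >= 2.
#' @return Recovered message value(s).
#' @export
iqun <- function(stego_coeff, beta) {
  if (any(beta < 2)) stop("parameter error: beta must be >= 2")
  k <- pmin(floor(abs(stego_coeff) * beta / 4), beta - 1)
  abs(stego_coeff) * beta / 4 - k
}

# Project coefficients onto the nearest magnitude whose within-cell
# position lies in the bit-correct band; sign is preserved (it carries no
# message). Bands are inset from the cell walls so integer rounding cannot
# cross a bit boundary afterwards.
project_band <- function(coeff, bit1, beta, band = c(0.08, 0.42)) {
  x <- abs(coeff) * beta / 4
  lo <- ifelse(bit1, 0.5 + band[1], band[1])
  hi <- ifelse(bit1, 0.5 + band[2], band[2])
  j <- floor(x)
  f <- x - j
  inside <- f >= lo & f <= hi
  # candidate positions in neighbouring cells, pick nearest, magnitude >= 0
  c1 <- j + lo
  c2 <- j + hi
  c3 <- pmax(j - 1, 0) + hi
  c4 <- j + 1 + lo
  pick <- function(cand, cur) ifelse(abs(cand - x) < abs(cur - x), cand, cur)
  best <- c1
  best <- pick(c2, best)
  best <- pick(c3, best)
  best <- pick(c4, best)
  x_new <- ifelse(inside, x, best)
  sign_c <- ifelse(coeff < 0, -1, 1)
  sign_c * x_new * 4 / beta
}

# smallest valid quantizer output (signed) that is >= target, for message
# level m: the valid set is {±4(j+m)/beta, j = 0, 1, ...}
next_valid_coeff_up <- function(target, m, beta) {
  x <- target * beta / 4
  j_pos <- max(0, ceiling(x - m - 1e-12))
  cand <- 4 * (j_pos + m) / beta
  if (target <= 0) {
    j_neg <- floor(-x - m)
    if (j_neg >= 0) {
      neg <- -4 * (j_neg + m) / beta
      if (neg >= target) cand <- neg
    }
  }
  cand
}

next_valid_coeff_down <- function(target, m, beta) {
  -next_valid_coeff_up(-target, m, beta)
}

# Repair quantized tiles whose IDCT leaves the representable pixel box
# (near-black tiles undershooting 0, bright tiles overshooting the integer
# ceiling). Three stages per tile, cheapest first:
#   1. flip signs of AC coefficients (the sign carries no message and the
#      cover sign of a near-zero coefficient is noise) to shrink the
#      waveform's peak-to-peak range;
#   2. lift (or lower) the DC coefficient to the nearest valid quantizer
#      level that moves every pixel inside the box -- exact, and leaves the
#      other 15 recovered values untouched;
#   3. alternating projections between the pixel box and the bit-correct
#      coefficient bands, as a fallback for tiles too energetic for 1+2.
# `eps` keeps a safety margin of a couple of integer steps so rounding
# never clamps.
refine_tiles <- function(tiles, msg, beta, lo, hi, eps, maxit = 200L) {
  nbad <- ncol(tiles)
  coeffs <- .dct16 %*% tiles
  for (t in seq_len(nbad)) {
    co <- coeffs[, t]
    p <- tiles[, t]
    # stage 1: greedy sign flips on AC coefficients
    if (min(p) < lo + eps || max(p) > hi - eps) {
      for (pass in 1:2) {
        for (j in 2:16) {
          if (co[j] == 0) next
          p2 <- p - 2 * co[j] * .dct16[j, ]
          if (diff(range(p2)) < diff(range(p))) {
            co[j] <- -co[j]
            p <- p2
          }
        }
      }
    }
    # stage 2: DC adjustment
    m_dc <- iqun(co[1], beta)
    if (min(p) < lo + eps) {
      delta <- (lo + eps) - min(p)
      dc_new <- next_valid_coeff_up(co[1] + 4 * delta, m_dc, beta)
      p <- p + (dc_new - co[1]) / 4
      co[1] <- dc_new
    }
    if (max(p) > hi - eps) {
      delta <- max(p) - (hi - eps)
      dc_new <- next_valid_coeff_down(co[1] - 4 * delta, m_dc, beta)
      p2 <- p + (dc_new - co[1]) / 4
      if (min(p2) >= lo + eps / 2) {
        p <- p2
        co[1] <- dc_new
      }
    }
    # stage 3: alternating projections if the box is still violated
    if (min(p) < lo || max(p) > hi) {
      bit1 <- msg[, t] >= 0.5
      for (it in seq_len(maxit)) {
        pc <- pmin(pmax(p, lo + eps), hi - eps)
        cc <- .dct16 %*% pc
        cp <- project_band(cc, bit1, beta)
        p <- as.vector(crossprod(.dct16, cp))
        if (all(p >= lo & p <= hi)) break
      }
      p <- pmin(pmax(p, lo), hi)
    }
    tiles[, t] <- p
  }
  tiles
}

#' Embed a message into the insignificant region of a cover
#'
#' The cover is min-max normalized, the mask's embeddable 4x4 tiles are
#' enumerated, and each message block is written into the next tile by
#' replacing the within-cell position of every DCT coefficient with the
#' block's corresponding message value ([qun()]), then inverting the
#' transform. Tiles whose quantized pixels would leave the representable
#' integer range are refined by alternating projections so that the
#' stored integers still decode to the correct bits. Finally the image is
#' de-normalized; a 16-bit cover keeps its exact affine map (untouched
#' pixels stay bit-identical), while a 12-bit cover's stego is written
#' into the full 16-bit range, whose finer integer grid preserves the
#' quantizer's decision margin.
#'
#' @param cover A [medical_image()].
#' @param mask A [binary_mask()] for the cover (1 = significant, never
#'   touched).
#' @param msg_blocks A `message_blocks` from [blockify_message()].
#' @param key An [embedding_key()].
#' @param verify Run extraction internally and record whether every bit
#'   survives (`manifest$verified`).
#' @return A `stego_result`: list with `stego` (a [medical_image()]) and
#'   `manifest` (normalization parameters, key material, `tiles_used`,
#'   `verified`).
#' @export
embed_payload <- function(cover, mask, msg_blocks, key = embedding_key(),
                          verify = TRUE) {
  stopifnot(inherits(cover, "medical_image"), inherits(mask, "binary_mask"),
            inherits(msg_blocks, "message_blocks"))
  if (!identical(dim(cover$pixels), dim(mask$labels))) {
    stop("alignment error: cover and mask shapes differ")
  }
  plan <- plan_tiles(mask, key)
  nb <- length(msg_blocks$blocks)
  if (nb > nrow(plan$tile_origins)) {
    stop(sprintf("capacity error: message needs %d tiles but only %d are available",
                 nb, nrow(plan$tile_origins)))
  }
  nimg <- normalize_image(cover)
  # encoding map for the stego integers: exact inverse for 16-bit covers;
  # a 12-bit cover's stego is written into 16 bits via an exact 4-bit
  # shift (values x16), whose finer integer grid keeps pixel rounding
  # below the quantizer's decision margin while every untouched pixel
  # remains exactly recoverable (and every intensity relation, including
  # the mask threshold, is scale-invariant)
  shift <- if (cover$bit_depth == 16L) 1 else 16
  enc_min <- shift * nimg$norm_min
  enc_max <- shift * nimg$norm_max
  out_depth <- 16L
  lim <- 2^out_depth - 1
  lo <- (0 - enc_min) / (enc_max - enc_min)
  hi <- (lim - enc_min) / (enc_max - enc_min)

  values <- nimg$values
  if (nb > 0L) {
    origins <- plan$tile_origins[seq_len(nb), , drop = FALSE]
    idx <- tile_indices(origins, dim(values))
    tiles <- matrix(values[idx], nrow = 16L)
    msg_mat <- vapply(msg_blocks$blocks, as.vector, numeric(16L))
    coeffs <- .dct16 %*% tiles
    st_coeffs <- qun(coeffs, msg_mat, key$beta)
    st_tiles <- crossprod(.dct16, st_coeffs)

    eps <- 2 / (enc_max - enc_min)
    bad <- which(colSums(st_tiles < lo + eps | st_tiles > hi - eps) > 0L)
    if (length(bad) > 0L) {
      st_tiles[, bad] <- refine_tiles(st_tiles[, bad, drop = FALSE],
                                      msg_mat[, bad, drop = FALSE],
                                      key$beta, lo, hi, eps)
    }
    values[idx] <- st_tiles
  }

  px <- round_half_away(values * (enc_max - enc_min) + enc_min)
  px[px < 0] <- 0
  px[px > lim] <- lim
  stego <- medical_image(px, bit_depth = out_depth, modality = cover$modality)

  key$message_shape <- msg_blocks$original_shape
  manifest <- list(
    norm_min = enc_min, norm_max = enc_max,
    cover_min = nimg$norm_min, cover_max = nimg$norm_max,
    cover_bit_depth = cover$bit_depth, stego_bit_depth = out_depth,
    beta = key$beta, alpha = key$alpha,
    message_shape = msg_blocks$original_shape,
    module_scale = msg_blocks$module_scale,
    tile_order_seed = key$tile_order_seed,
    tiles_used = nb, verified = NA
  )
  if (verify && nb > 0L) {
    rec <- extract_payload(stego, mask, key,
                           manifest_norm = c(enc_min, enc_max),
                           module_scale = msg_blocks$module_scale)
    want <- unblockify_and_decide(msg_blocks)
    got <- unblockify_and_decide(rec)
    manifest$verified <- identical(want$bits, got$bits)
    if (!manifest$verified) {
      warning("verification failed: extracted bits differ from embedded bits")
    }
  } else if (nb == 0L) {
    manifest$verified <- TRUE
  }
  structure(list(stego = stego, manifest = manifest), class = "stego_result")
}

# linear indices of the 16 pixels of each tile (16 x ntiles)
tile_indices <- function(origins, shape) {
  nr <- shape[1]
  off <- as.vector(outer(0:3, 0:3, function(r, c) r + nr * c))  # column-major 4x4
  base <- origins[, 1] + nr * (origins[, 2] - 1L)
  outer(off, base, `+`)
}

#' Extract a hidden message from a stego image
#'
#' The stego image is normalized with the manifest's parameters, the tile
#' plan is recomputed from the (stego-derived) mask, and the within-cell
#' position of each coefficient is read back ([iqun()]).
#'
#' @param stego The stego [medical_image()].
#' @param mask A [binary_mask()] computed from the stego image (the
#'   extraction-side segmenter; masks are not transmitted).
#' @param key The [embedding_key()] used at embedding (must carry
#'   `message_shape`).
#' @param manifest_norm `c(norm_min, norm_max)` from the embedding
#'   manifest.
#' @param module_scale Module scale to stamp on the recovered message.
#' @return A `message_blocks` of recovered real values.
#' @export
extract_payload <- function(stego, mask, key, manifest_norm,
                            module_scale = 1L) {
  stopifnot(inherits(stego, "medical_image"), inherits(mask, "binary_mask"))
  if (is.null(key$message_shape)) stop("key must carry message_shape")
  shape <- key$message_shape
  tr <- ceiling(shape[1] / 4L); tc <- ceiling(shape[2] / 4L)
  nb <- tr * tc
  plan <- plan_tiles(mask, key)
  if (nb > nrow(plan$tile_origins)) {
    stop(sprintf("truncation error: message needs %d tiles but the mask offers %d",
                 nb, nrow(plan$tile_origins)))
  }
  values <- (stego$pixels - manifest_norm[1]) / (manifest_norm[2] - manifest_norm[1])
  origins <- plan$tile_origins[seq_len(nb), , drop = FALSE]
  idx <- tile_indices(origins, dim(values))
  tiles <- matrix(values[idx], nrow = 16L)
  coeffs <- .dct16 %*% tiles
  rec <- iqun(coeffs, key$beta)
  blocks <- lapply(seq_len(nb), function(i) matrix(rec[, i], 4L, 4L))
  structure(list(blocks = blocks, original_shape = as.integer(shape),
                 alpha = key$alpha, module_scale = as.integer(module_scale)),
            class = "message_blocks")
}

#' Capacity accounting for a mask
#'
#' One bit per insignificant pixel: every planned 4x4 tile carries 16
#' message values, one per DCT coefficient.
#'
#' @param mask A [binary_mask()].
#' @param guard_radius Guard margin passed to [plan_tiles()]; the default
#'   matches what [embed_payload()] uses, so `capacity_bits` is exactly
#'   what can be embedded. Set 0 for raw one-bit-per-background-pixel
#'   accounting.
#' @return List with `usable_fraction` (insignificant pixels / total),
#'   `capacity_bits` (planned tiles x 16) and `capacity_bpp`
#'   (bits / total pixels).
#' @export
capacity_report <- function(mask, guard_radius = 8L) {
  stopifnot(inherits(mask, "binary_mask"))
  total <- length(mask$labels)
  plan <- plan_tiles(mask, guard_radius = guard_radius)
  bits <- 16L * nrow(plan$tile_origins)
  list(usable_fraction = mean(mask$labels == 0),
       capacity_bits = bits,
       capacity_bpp = bits / total)
}

#' Write an embedding manifest as a JSON sidecar
#' @param manifest Manifest list from a `stego_result`.
#' @param path Output path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read an embedding manifest written by [write_manifest()]
#' @param path Manifest path.
#' @return Manifest list.
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c("norm_min", "norm_max", "beta", "alpha", "message_shape")
  missing <- setdiff(required, names(m))
  if (length(missing) > 0) {
    stop("manifest missing required fields: ", paste(missing, collapse = ", "))
  }
  m
}
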