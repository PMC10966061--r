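# run code under a temporary RNG state, restoring the caller's
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Specification for a synthetic phantom
#'
#' Describes a CT-like (512x512, 16-bit) or MR-like (256x256, 12-bit)
#' abdominal slice: near-black noisy background plus a few bright, smoothly
#' textured organ-like blobs with a known ground-truth mask.
#'
#' @param shape `c(rows, cols)`, both divisible by 4.
#' @param bit_depth 12 or 16.
#' @param modality_style `"CT"` or `"MR"`.
#' @param n_blobs Number of elliptical foreground blobs.
#' @param background_noise_level Background amplitude bound in units of
#'   `0.01 * R`: all background values stay at or below
#'   `background_noise_level * R / 100`.
#' @param seed Integer seed; the phantom is deterministic given the seed.
#' @param fg_range Acceptable foreground fraction; placement is retried (up
#'   to 10 attempts) until the blob union lands inside it.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(512L, 512L), bit_depth = 16L,
                         modality_style = c("CT", "MR"), n_blobs = 3L,
                         background_noise_level = 2, seed = 1L,
                         fg_range = c(0.3, 0.6)) {
  modality_style <- match.arg(modality_style)
  if (any(shape %% 4L != 0L)) stop("shape must be divisible by 4")
  if (!bit_depth %in% c(12L, 16L)) stop("bit_depth must be 12 or 16")
  if (n_blobs < 1L) stop("n_blobs must be >= 1")
  if (background_noise_level < 0) stop("background_noise_level must be >= 0")
  structure(list(shape = as.integer(shape), bit_depth = as.integer(bit_depth),
                 modality_style = modality_style, n_blobs = as.integer(n_blobs),
                 background_noise_level = background_noise_level,
                 seed = as.integer(seed), fg_range = fg_range),
            class = "phantom_spec")
}

#' Convenience spec for a CT-like 512x512 16-bit phantom
#' @param seed Integer seed.
#' @param ... Passed to [phantom_spec()].
#' @export
ct_phantom_spec <- function(seed = 1L, ...) {
  phantom_spec(shape = c(512L, 512L), bit_depth = 16L, modality_style = "CT",
               seed = seed, ...)
}

#' Convenience spec for an MR-like 256x256 12-bit phantom
#' @param seed Integer seed.
#' @param ... Passed to [phantom_spec()].
#' @export
mr_phantom_spec <- function(seed = 1L, ...) {
  phantom_spec(shape = c(256L, 256L), bit_depth = 12L, modality_style = "MR",
               seed = seed, ...)
}

#' Generate a synthetic phantom cover with ground-truth mask
#'
#' Blobs are rotated ellipses with a bright, gently textured plateau
#' (about 55-65% of the representable peak, leaving integer headroom above
#' the cover maximum for embedding overshoot) and a sharp ~2-pixel edge, so
#' that thresholding at any reasonable level recovers essentially the same
#' region. The background is low-amplitude truncated Gaussian noise around a
#' small positive baseline (detector/air noise); the exact support of the
#' blob union is returned as the ground-truth significant mask.
#'
#' @param spec A [phantom_spec()].
#' @return List with `image` (a [medical_image()]) and `mask` (a
#'   [binary_mask()], 1 = blob).
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    nr <- spec$shape[1]; nc <- spec$shape[2]
    R <- 2^spec$bit_depth - 1
    rr <- matrix(seq_len(nr), nr, nc)
    cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)

    inside <- NULL
    dist_out <- NULL
    for (attempt in seq_len(10L)) {
      # elliptic "radius" field of each blob: d < 1 inside
      d_min <- matrix(Inf, nr, nc)      # min over blobs of elliptic distance
      scale <- min(nr, nc)
      for (b in seq_len(spec$n_blobs)) {
        big <- b == 1L
        a_ax <- scale * (if (big) stats::runif(1, 0.27, 0.35) else stats::runif(1, 0.15, 0.23))
        b_ax <- a_ax * stats::runif(1, 0.65, 0.9)
        th <- stats::runif(1, 0, pi)
        cx <- nr * stats::runif(1, 0.3, 0.7)
        cy <- nc * stats::runif(1, 0.3, 0.7)
        u <- (rr - cx) * cos(th) + (cc - cy) * sin(th)
        v <- -(rr - cx) * sin(th) + (cc - cy) * cos(th)
        d <- sqrt((u / a_ax)^2 + (v / b_ax)^2)
        # absolute distance to the blob edge, approximated along the gradient
        d_edge <- (d - 1) * sqrt(a_ax * b_ax)
        d_min <- pmin(d_min, d_edge)
      }
      inside <- d_min < 0
      frac <- mean(inside)
      if (frac >= spec$fg_range[1] && frac <= spec$fg_range[2]) break
      if (attempt == 10L) {
        stop(sprintf("phantom placement failed: foreground fraction %.2f outside [%.2f, %.2f] after 10 attempts",
                     frac, spec$fg_range[1], spec$fg_range[2]))
      }
    }

    # sharp edge: ~2 px roll-off inside the boundary, exact zero outside,
    # so the ground-truth support is also the intensity support and the
    # background stays within its amplitude bound
    edge_w <- 2
    profile <- stats::plogis(-d_min, scale = edge_w / 4) * (d_min < 0)

    # low-frequency multiplicative texture on the foreground
    tex <- matrix(0, nr, nc)
    for (k in seq_len(4L)) {
      fx <- stats::runif(1, 0.5, 2.5) * pi / nr
      fy <- stats::runif(1, 0.5, 2.5) * pi / nc
      tex <- tex + cos(fx * rr + stats::runif(1, 0, 2 * pi)) *
        cos(fy * cc + stats::runif(1, 0, 2 * pi))
    }
    tex <- 1 + 0.06 * tex / 2
    peak <- R * stats::runif(1, 0.58, 0.66)

    # background: truncated gaussian noise around a small positive baseline,
    # bounded by background_noise_level * R / 100
    bg_cap <- spec$background_noise_level * R / 100
    base <- 0.6 * bg_cap
    noise <- base + stats::rnorm(nr * nc, 0, 0.12 * bg_cap)
    noise <- pmin(pmax(noise, 0), bg_cap)
    bg <- matrix(noise, nr, nc)

    img <- bg + peak * tex * profile
    px <- round_half_away(pmin(pmax(img, 0), R))
    list(image = medical_image(px, bit_depth = spec$bit_depth,
                               modality = if (spec$modality_style == "CT") "CT" else "MR"),
         mask = binary_mask(inside * 1))
  })
}

#' Generate a synthetic patient record
#'
#' Plausible but entirely fictitious demographics (never real PHI), short
#' enough to fit the default QR version/error-correction settings.
#'
#' @param seed Integer seed; the record is deterministic given the seed and
#'   records from different seeds carry distinct patient IDs.
#' @return A single UTF-8 string.
#' @export
generate_patient_record <- function(seed = 1L) {
  first <- c("Alex", "Sam", "Jo", "Chris", "Dana", "Lee", "Noa", "Kim",
             "Max", "Ray", "Ida", "Ben")
  last <- c("Smith", "Lopez", "Chen", "Okafor", "Novak", "Haddad", "Kumar",
            "Berg", "Rossi", "Diaz", "Kato", "Mbeki")
  with_seed(seed, {
    sprintf("Name: %s %s; ID: P%08d; Age: %d; Mod: %s; Date: 2024-%02d-%02d",
            sample(first, 1), sample(last, 1),
            seed %% 100000000L,
            sample(18:90, 1),
            sample(c("CT", "MR"), 1),
            sample(1:12, 1), sample(1:28, 1))
  })
}
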