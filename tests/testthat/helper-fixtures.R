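# Shared fixtures, generated in code and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

ct_fixture <- function(seed = 1L) {
  fixture(paste0("ct", seed), generate_phantom(ct_phantom_spec(seed = seed)))
}

mr_fixture <- function(seed = 1L) {
  fixture(paste0("mr", seed), generate_phantom(mr_phantom_spec(seed = seed)))
}

# small random 16-bit test image
random_image <- function(seed, nr = 16L, nc = 16L, bit_depth = 16L) {
  set.seed(seed)
  medical_image(matrix(sample(0:(2^bit_depth - 1), nr * nc, replace = TRUE), nr, nc),
                bit_depth = bit_depth)
}

# brute-force double-sum type-II DCT with orthonormal scaling; the
# independent oracle for the fast matrix implementation
dct2_bruteforce <- function(block) {
  M <- nrow(block); N <- ncol(block)
  a <- function(u, n) if (u == 0) sqrt(1 / n) else sqrt(2 / n)
  out <- matrix(0, M, N)
  for (u in 0:(M - 1)) for (v in 0:(N - 1)) {
    s <- 0
    for (m in 0:(M - 1)) for (n in 0:(N - 1)) {
      s <- s + block[m + 1, n + 1] *
        cos((2 * m + 1) * u * pi / (2 * M)) *
        cos((2 * n + 1) * v * pi / (2 * N))
    }
    out[u + 1, v + 1] <- a(u, M) * a(v, N) * s
  }
  out
}

idct2_bruteforce <- function(coeffs) {
  M <- nrow(coeffs); N <- ncol(coeffs)
  a <- function(u, n) if (u == 0) sqrt(1 / n) else sqrt(2 / n)
  out <- matrix(0, M, N)
  for (m in 0:(M - 1)) for (n in 0:(N - 1)) {
    s <- 0
    for (u in 0:(M - 1)) for (v in 0:(N - 1)) {
      s <- s + a(u, M) * a(v, N) * coeffs[u + 1, v + 1] *
        cos((2 * m + 1) * u * pi / (2 * M)) *
        cos((2 * n + 1) * v * pi / (2 * N))
    }
    out[m + 1, n + 1] <- s
  }
  out
}

# full pipeline helper: embed into a phantom, reread via DICOM, extract
# with a stego-derived mask, and report bit accuracy plus decoded text
roundtrip_via_dicom <- function(ph, record, beta) {
  mask <- threshold_mask(ph$image)
  qr <- text_to_qr(record)
  blocks <- blockify_message(adjust_message(qr))
  key <- embedding_key(beta = beta)
  res <- embed_payload(ph$image, mask, blocks, key, verify = FALSE)
  path <- tempfile(fileext = ".dcm")
  on.exit(unlink(path))
  write_image(res$stego, path)
  back <- read_image(path)
  key$message_shape <- blocks$original_shape
  rec <- extract_payload(back, threshold_mask(back), key,
                         manifest_norm = c(res$manifest$norm_min, res$manifest$norm_max),
                         module_scale = 4L)
  got <- unblockify_and_decide(rec)
  list(
    bit_accuracy = mean(got$bits == qr$bits),
    text = tryCatch(qr_to_text(got), error = function(e) NA_character_),
    stego = res$stego, manifest = res$manifest, qr = qr, mask = mask
  )
}
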