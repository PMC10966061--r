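test_that("dct2/idct2 agree with the brute-force double-sum oracle", {
  # constant block: DC = 4c under orthonormal scaling, all others 0
  cblock <- matrix(0.37, 4, 4)
  co <- dct2(cblock)
  expect_equal(co[1, 1], 4 * 0.37, tolerance = 1e-12)
  expect_equal(max(abs(co[-1])), 0, tolerance = 1e-12)
  expect_equal(dct2(matrix(0, 4, 4)), matrix(0, 4, 4))
  expect_equal(idct2(matrix(c(4, rep(0, 15)), 4, 4)), matrix(1, 4, 4),
               tolerance = 1e-12)

  set.seed(8)
  for (rep in 1:25) {
    b <- matrix(runif(16), 4, 4)
    expect_equal(dct2(b), dct2_bruteforce(b), tolerance = 1e-12)
    expect_equal(idct2(dct2(b)), b, tolerance = 1e-12)
    expect_equal(idct2_bruteforce(dct2(b)), b, tolerance = 1e-12)
    # Parseval (orthonormality)
    expect_equal(sum(b^2), sum(dct2(b)^2), tolerance = 1e-12)
  }
})

test_that("qun follows the reconciled quantization rule", {
  expect_equal(qun(0.6, 0.98, 8), 0.99)   # k = 1, 0.5 + 0.5 * 0.98
  expect_equal(qun(0.6, 0.02, 8), 0.51)
  expect_equal(qun(-0.6, 0.98, 8), -0.99) # sign preserved
  # output stays strictly inside cell k
  set.seed(13)
  cc <- runif(500, -4, 4)
  for (m in c(0.02, 0.98)) {
    out <- qun(cc, m, 8)
    k <- pmin(floor(abs(cc) * 2), 7)
    expect_true(all(abs(out) > k / 2 & abs(out) < (k + 1) / 2))
  }
  expect_error(qun(0.5, 1.2, 8), "message values")
  expect_error(qun(0.5, 0.5, 1), "beta")
})

test_that("iqun is the exact left inverse of qun", {
  expect_equal(iqun(0.99, 8), 0.98)
  expect_equal(iqun(0.51, 8), 0.02)
  set.seed(14)
  cc <- runif(2000, -4, 4)
  betas <- sample(2:2000, 2000, replace = TRUE)
  for (m in c(0.02, 0.98)) {
    expect_equal(iqun(qun(cc, m, betas[1]), betas[1]), rep(m, 2000),
                 tolerance = 1e-9)
    rec <- vapply(seq_along(cc), function(i) iqun(qun(cc[i], m, betas[i]), betas[i]),
                  numeric(1))
    expect_equal(rec, rep(m, 2000), tolerance = 1e-9)
  }
})

test_that("plan_tiles enumerates clear 4-aligned tiles row-major", {
  none <- binary_mask(matrix(1, 8, 8))
  expect_equal(nrow(plan_tiles(none)$tile_origins), 0)

  all_bg <- binary_mask(matrix(0, 8, 8))
  p <- plan_tiles(all_bg)
  expect_equal(nrow(p$tile_origins), 4)
  expect_equal(p$tile_origins[, "row"], c(1, 1, 5, 5))
  expect_equal(p$tile_origins[, "col"], c(1, 5, 1, 5))

  # one significant pixel excludes exactly its tile (no guard)
  one <- matrix(0, 8, 8); one[1, 1] <- 1
  p1 <- plan_tiles(binary_mask(one), guard_radius = 0L)
  expect_equal(nrow(p1$tile_origins), 3)
  expect_false(any(p1$tile_origins[, 1] == 1 & p1$tile_origins[, 2] == 1))

  # guard ring also excludes neighbouring tiles
  p2 <- plan_tiles(binary_mask(one), guard_radius = 8L)
  expect_equal(nrow(p2$tile_origins), 0)

  # seeded permutation is deterministic and a permutation
  big <- binary_mask(matrix(0, 16, 16))
  k <- embedding_key(tile_order_seed = 5L)
  pa <- plan_tiles(big, k); pb <- plan_tiles(big, k)
  expect_identical(pa$tile_origins, pb$tile_origins)
  expect_setequal(paste(pa$tile_origins[, 1], pa$tile_origins[, 2]),
                  paste(plan_tiles(big)$tile_origins[, 1],
                        plan_tiles(big)$tile_origins[, 2]))
})

test_that("capacity accounting is one bit per insignificant pixel", {
  all_bg <- binary_mask(matrix(0, 64, 64))
  cap <- capacity_report(all_bg)
  expect_equal(cap$usable_fraction, 1)
  expect_equal(cap$capacity_bits, 64 * 64)
  expect_equal(cap$capacity_bpp, 1)

  none <- binary_mask(matrix(1, 64, 64))
  expect_equal(capacity_report(none)$capacity_bits, 0)

  # half the tiles available -> bpp 0.5 exactly (guard-free accounting);
  # with the embedder's guard ring the margin tiles drop out too
  half <- matrix(0, 64, 64)
  half[1:32, ] <- 1
  expect_equal(capacity_report(binary_mask(half), guard_radius = 0L)$capacity_bpp, 0.5)
  expect_equal(capacity_report(binary_mask(half))$capacity_bpp, (64 - 32 - 8) / 64)
})

test_that("zero-payload embedding is the identity and embedding is local", {
  ph <- ct_fixture(1)
  mask <- threshold_mask(ph$image)
  empty <- structure(list(blocks = list(), original_shape = c(0L, 0L),
                          alpha = 0.02, module_scale = 1L),
                     class = "message_blocks")
  res0 <- embed_payload(ph$image, mask, empty, embedding_key())
  expect_identical(res0$stego$pixels, ph$image$pixels)
  expect_equal(compute_psnr(ph$image, res0$stego), Inf)

  qr <- text_to_qr(generate_patient_record(1))
  blocks <- blockify_message(adjust_message(qr))
  res <- embed_payload(ph$image, mask, blocks, embedding_key(), verify = FALSE)
  plan <- plan_tiles(mask, embedding_key())
  used <- plan$tile_origins[seq_along(blocks$blocks), , drop = FALSE]
  idx <- stegomed:::tile_indices(used, dim(ph$image$pixels))
  outside <- setdiff(seq_along(ph$image$pixels), as.vector(idx))
  expect_identical(res$stego$pixels[outside], ph$image$pixels[outside])
  expect_true(any(res$stego$pixels[as.vector(idx)] != ph$image$pixels[as.vector(idx)]))
})

test_that("insufficient capacity is a capacity error naming the shortfall", {
  ph <- ct_fixture(1)
  tiny <- binary_mask(matrix(1, 512, 512))  # nothing embeddable
  qr <- text_to_qr("x")
  blocks <- blockify_message(adjust_message(qr))
  expect_error(embed_payload(ph$image, tiny, blocks, embedding_key()),
               "capacity error.*tiles")
})

test_that("extraction with the wrong beta fails QR decoding", {
  ph <- mr_fixture(1)
  mask <- threshold_mask(ph$image)
  rec <- generate_patient_record(2)
  qr <- text_to_qr(rec)
  blocks <- blockify_message(adjust_message(qr))
  res <- embed_payload(ph$image, mask, blocks, embedding_key(beta = 500L),
                       verify = FALSE)
  wrong <- embedding_key(beta = 250L, message_shape = blocks$original_shape)
  out <- extract_payload(res$stego, threshold_mask(res$stego), wrong,
                         c(res$manifest$norm_min, res$manifest$norm_max), 4L)
  expect_error(qr_to_text(unblockify_and_decide(out)), "decode")
})

test_that("manifests round-trip through JSON", {
  ph <- mr_fixture(1)
  mask <- threshold_mask(ph$image)
  qr <- text_to_qr("ID:77")
  blocks <- blockify_message(adjust_message(qr))
  res <- embed_payload(ph$image, mask, blocks, embedding_key())
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_manifest(res$manifest, path)
  m <- read_manifest(path)
  expect_equal(m$beta, 1000)
  expect_equal(m$norm_min, res$manifest$norm_min)
  expect_equal(m$message_shape, res$manifest$message_shape)
  expect_true(m$verified)
  # missing fields are named
  jsonlite::write_json(list(beta = 1), path, auto_unbox = TRUE)
  expect_error(read_manifest(path), "norm_min")
})
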