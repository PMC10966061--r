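test_that("MSE matches hand evaluation and is symmetric", {
  a <- medical_image(matrix(0, 8, 8))
  b <- medical_image(matrix(c(3, 4, rep(0, 62)), 8, 8))
  expect_equal(compute_mse(a, b), (9 + 16) / 64)
  expect_equal(compute_mse(a, a), 0)
  x <- random_image(1); y <- random_image(2)
  expect_equal(compute_mse(x, y), compute_mse(y, x))
  expect_error(compute_mse(a, medical_image(matrix(0, 16, 16))), "alignment")
})

test_that("PSNR satisfies its closed form and scaling law", {
  a <- medical_image(matrix(0, 8, 8))
  expect_equal(compute_psnr(a, a), Inf)

  # MSE = 1 at 16 bits -> 10 log10(65535^2) = 96.33 dB
  b <- a; b$pixels[] <- 0; b$pixels[1:64] <- 1
  expect_equal(compute_psnr(a, b), 10 * log10(65535^2))
  expect_equal(round(compute_psnr(a, b), 2), 96.33)

  # doubling every difference costs 20 log10(2) dB
  d1 <- medical_image(matrix(10, 8, 8)); d2 <- medical_image(matrix(20, 8, 8))
  expect_equal(compute_psnr(a, d1) - compute_psnr(a, d2), 20 * log10(2))

  # 12-bit peak is 4095
  p <- medical_image(matrix(c(1, rep(0, 63)), 8, 8), 12L)
  z <- medical_image(matrix(0, 8, 8), 12L)
  expect_equal(compute_psnr(z, p), 10 * log10(4095^2 / (1 / 64)))
  expect_error(compute_psnr(a, z), "bit depths")
})

test_that("null attacks are identities and attacks are seeded", {
  img <- random_image(20, 32L, 32L)
  for (spec in list(attack_spec("gaussian", sigma = 0),
                    attack_spec("uniform", half_width = 0),
                    attack_spec("salt_pepper", density = 0))) {
    expect_identical(apply_attack(img, spec)$pixels, img$pixels)
  }
  sp <- attack_spec("salt_pepper", density = 1, seed = 3)
  out <- apply_attack(img, sp)
  expect_true(all(out$pixels %in% c(0, 65535)))

  g <- attack_spec("gaussian", sigma = 50, seed = 9)
  expect_identical(apply_attack(img, g)$pixels, apply_attack(img, g)$pixels)
  expect_false(identical(apply_attack(img, attack_spec("gaussian", sigma = 50, seed = 10))$pixels,
                         apply_attack(img, g)$pixels))
})

test_that("empirical gaussian attack MSE approaches sigma squared", {
  set.seed(30)
  img <- medical_image(matrix(sample(20000:40000, 1024 * 1024, replace = TRUE), 1024))
  s <- 300
  out <- apply_attack(img, attack_spec("gaussian", sigma = s, seed = 4))
  expect_equal(compute_mse(img, out), s^2, tolerance = 0.05)
})

test_that("a null-attack robustness trial is perfect and deterministic", {
  ph <- mr_fixture(1)
  mask <- threshold_mask(ph$image)
  msg <- adjust_message(text_to_qr(generate_patient_record(5)))
  tr <- robustness_trial(ph$image, mask, msg, embedding_key(),
                         attack_spec("gaussian", sigma = 0))
  expect_equal(tr$ncc_message, 1, tolerance = 1e-4)
  expect_equal(tr$bit_accuracy, 1)
  expect_true(tr$decoded)

  spec <- attack_spec("salt_pepper", density = 0.003, seed = 11)
  t1 <- robustness_trial(ph$image, mask, msg, embedding_key(), spec)
  t2 <- robustness_trial(ph$image, mask, msg, embedding_key(), spec)
  expect_identical(t1, t2)
})

test_that("an extreme attack destroys the message", {
  ph <- mr_fixture(1)
  mask <- threshold_mask(ph$image)
  msg <- adjust_message(text_to_qr(generate_patient_record(5)))
  tr <- robustness_trial(ph$image, mask, msg, embedding_key(),
                         attack_spec("gaussian", sigma = 3000, seed = 2),
                         mask_provider = function(im) threshold_mask(im))
  expect_lt(abs(tr$ncc_message), 0.3)
  expect_false(tr$decoded)
})
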