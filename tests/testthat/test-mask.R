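test_that("IoU matches hand-enumerated overlaps and its conventions", {
  a <- binary_mask(matrix(c(1, 1, 1, 0), 2, 2))
  b <- binary_mask(matrix(c(1, 0, 0, 0), 2, 2))
  expect_equal(compute_iou(a, b), 1 / 3)  # |intersection| 1, |union| 3
  expect_equal(compute_iou(a, a), 1)
  expect_equal(compute_iou(b, a), compute_iou(a, b))

  disjoint <- binary_mask(matrix(c(0, 0, 0, 1), 2, 2))
  expect_equal(compute_iou(b, disjoint), 0)

  empty <- binary_mask(matrix(0, 2, 2))
  expect_equal(compute_iou(empty, empty), 1)  # both agree nothing is significant

  expect_error(compute_iou(a, binary_mask(matrix(0, 3, 3))), "alignment")
})

test_that("NCC matches the hand-summation oracle and is affine-invariant", {
  ncc_oracle <- function(a, b) {
    da <- a - mean(a); db <- b - mean(b)
    sum(da * db) / (sqrt(sum(da^2)) * sqrt(sum(db^2)))
  }
  a <- matrix(c(0, 0, 1, 1), 2, 2)
  b <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(compute_ncc(a, b), 0)
  expect_equal(compute_ncc(a, b), ncc_oracle(a, b))

  set.seed(2)
  x <- matrix(rnorm(64), 8, 8)
  y <- matrix(rnorm(64), 8, 8)
  expect_equal(compute_ncc(x, y), ncc_oracle(x, y))
  expect_equal(compute_ncc(x, x), 1)
  expect_equal(compute_ncc(x, -x + 3), -1)
  expect_equal(compute_ncc(x, 2.5 * y + 7), compute_ncc(x, y))

  expect_error(compute_ncc(x, matrix(1, 8, 8)), "degenerate")
})

test_that("threshold provider handles flat frames and recovers phantom blobs", {
  dark <- medical_image(matrix(0, 16, 16))
  expect_true(all(threshold_mask(dark)$labels == 0))

  bright <- medical_image(matrix(60000, 16, 16))
  expect_true(all(threshold_mask(bright)$labels == 1))

  ph <- ct_fixture(1)
  m <- threshold_mask(ph$image, rel_threshold = 0.05)
  expect_gte(compute_iou(m, ph$mask), 0.95)
  m2 <- threshold_mask(ph$image)  # defaults
  expect_gte(compute_iou(m2, ph$mask), 0.95)
})

test_that("external masks import as 0/1 with shape checking", {
  m <- binary_mask(matrix(rep(c(0, 1), each = 32), 8, 8))
  path <- tempfile(fileext = ".png")
  on.exit(unlink(path))
  write_mask(m, path)
  back <- external_mask_adapter(path, c(8, 8))
  expect_identical(back$labels, m$labels)
  expect_error(external_mask_adapter(path, c(16, 16)), "alignment")

  all_on <- binary_mask(matrix(1, 8, 8))
  write_mask(all_on, path)
  expect_true(all(external_mask_adapter(path, c(8, 8))$labels == 1))
})

test_that("masks recomputed from stego images agree with the cover's", {
  ph <- ct_fixture(1)
  mask <- threshold_mask(ph$image)
  qr <- text_to_qr(generate_patient_record(1))
  blocks <- blockify_message(adjust_message(qr))
  for (beta in c(10, 1000)) {
    res <- embed_payload(ph$image, mask, blocks, embedding_key(beta = beta),
                         verify = FALSE)
    sm <- threshold_mask(res$stego)
    expect_gte(compute_iou(mask, sm), 0.99)
    expect_gte(compute_ncc(mask, sm), 0.99)
  }
})
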