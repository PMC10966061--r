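test_that("message adjustment maps bits to alpha levels", {
  qr <- qr_bitmap(rbind(c(0, 1), c(1, 0)) %x% matrix(1, 2, 2), 2L)
  adj <- adjust_message(qr, 0.02)
  expect_true(all(adj$values %in% c(0.02, 0.98)))
  expect_equal(adj$values[1, 1], 0.02)  # bit 0 -> alpha
  expect_equal(adj$values[1, 3], 0.98)  # bit 1 -> 1 - alpha
  expect_error(adjust_message(qr, 0.5), "alpha")
  expect_error(adjust_message(qr, 0), "alpha")
})

test_that("blockify pads to multiples of 4 and unblockify inverts it", {
  # 4x4: single block equal to the message
  m4 <- structure(list(values = matrix(0.98, 4, 4), alpha = 0.02,
                       module_scale = 1L), class = "adjusted_message")
  b4 <- blockify_message(m4)
  expect_length(b4$blocks, 1)
  expect_equal(b4$blocks[[1]], m4$values)

  # 8x4: two blocks, top tile first
  v <- rbind(matrix(0.98, 4, 4), matrix(0.02, 4, 4))
  m8 <- structure(list(values = v, alpha = 0.02, module_scale = 1L),
                  class = "adjusted_message")
  b8 <- blockify_message(m8)
  expect_length(b8$blocks, 2)
  expect_equal(b8$blocks[[1]], matrix(0.98, 4, 4))
  expect_equal(b8$blocks[[2]], matrix(0.02, 4, 4))

  # 5x5: padded to 8x8 (4 blocks), round-trip recovers the 5x5 exactly
  set.seed(3)
  bits <- matrix(sample(0:1, 25, replace = TRUE), 5, 5)
  msg <- adjust_message(qr_bitmap(bits, 1L), 0.02)
  b5 <- blockify_message(msg)
  expect_length(b5$blocks, 4)
  back <- unblockify_and_decide(b5)
  expect_identical(back$bits, bits + 0)
})

test_that("bit decision uses the 0.5 midpoint with ties to 1", {
  blocks <- structure(list(
    blocks = list(matrix(c(0.93, 0.07, 0.5, 0.499, rep(0.02, 12)), 4, 4)),
    original_shape = c(4L, 4L), alpha = 0.02, module_scale = 1L),
    class = "message_blocks")
  out <- unblockify_and_decide(blocks)
  expect_equal(out$bits[1, 1], 1)  # 0.93
  expect_equal(out$bits[2, 1], 0)  # 0.07
  expect_equal(out$bits[3, 1], 1)  # exact tie
  expect_equal(out$bits[4, 1], 0)  # just below
})

test_that("decision rule is symmetric under value inversion", {
  set.seed(6)
  vals <- matrix(runif(64), 8, 8)
  vals[vals == 0.5] <- 0.51
  mk <- function(v) {
    structure(list(blocks = blockify_message(v)$blocks,
                   original_shape = c(8L, 8L), alpha = NA_real_,
                   module_scale = 1L), class = "message_blocks")
  }
  a <- unblockify_and_decide(mk(vals))$bits
  b <- unblockify_and_decide(mk(1 - vals))$bits
  expect_identical(a + b, matrix(1, 8, 8))
})

test_that("adjust/blockify/unblockify is the identity on random bitmaps", {
  set.seed(12)
  for (rep in 1:20) {
    nr <- sample(4:40, 1); nc <- sample(4:40, 1)
    bits <- matrix(sample(0:1, nr * nc, replace = TRUE), nr, nc)
    out <- unblockify_and_decide(blockify_message(adjust_message(qr_bitmap(bits, 1L))))
    expect_identical(out$bits, bits + 0)
  }
})

test_that("patient records survive the full payload path", {
  rec <- generate_patient_record(99)
  expect_identical(qr_to_text(unblockify_and_decide(blockify_message(
    adjust_message(text_to_qr(rec))))), rec)
})
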