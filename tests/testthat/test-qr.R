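test_that("GF(256) arithmetic satisfies field identities", {
  set.seed(1)
  a <- sample(1:255, 50, replace = TRUE)
  b <- sample(1:255, 50, replace = TRUE)
  expect_equal(stegomed:::gf_mul(a, b), stegomed:::gf_mul(b, a))
  expect_equal(stegomed:::gf_mul(a, stegomed:::gf_inv(a)), rep(1L, 50))
  expect_equal(stegomed:::gf_mul(a, rep(1L, 50)), a)
})

test_that("Reed-Solomon corrects up to its budget and refuses beyond it", {
  set.seed(4)
  for (rep in 1:10) {
    data <- sample(0:255, 20)
    n_ec <- 16L  # corrects 8 codeword errors
    cw <- c(data, stegomed:::qr_rs_encode(data, n_ec))
    expect_identical(stegomed:::qr_rs_decode(cw, n_ec), as.integer(cw))
    k <- sample(1:8, 1)
    pos <- sample(length(cw), k)
    bad <- cw
    bad[pos] <- bitwXor(bad[pos], sample(1:255, k, replace = TRUE))
    expect_identical(stegomed:::qr_rs_decode(bad, n_ec), as.integer(cw))
  }
  # too many errors: must not silently return a wrong codeword
  data <- sample(0:255, 20)
  cw <- c(data, stegomed:::qr_rs_encode(data, 10L))
  bad <- cw
  bad[1:9] <- bitwXor(bad[1:9], rep(77L, 9))
  res <- stegomed:::qr_rs_decode(bad, 10L)
  expect_true(is.null(res) || identical(res, as.integer(cw)))
})

test_that("block structure tables are internally consistent", {
  for (v in 1:10) {
    for (lv in c("L", "M", "Q", "H")) {
      t <- stegomed:::qr_ec_table[[v]][[lv]]
      total <- sum(t$groups[, 1] * (t$groups[, 2] + t$ec))
      expect_equal(total, stegomed:::qr_total_codewords[v])
    }
  }
})

test_that("format information carries its standard fixed XOR", {
  # data 00000 (level M, mask 0) must produce the bare XOR mask 0x5412
  bits <- stegomed:::qr_format_bits("M", 0L)
  expect_equal(sum(bits * 2^(14:0)), 0x5412)
  # any two format words differ in >= 5 bits (BCH minimum distance)
  words <- sapply(c("L", "M", "Q", "H"), function(lv)
    sapply(0:7, function(k) stegomed:::qr_format_bits(lv, k) %*% 2^(14:0)))
  words <- as.vector(words)
  for (i in 1:31) for (j in (i + 1):32) {
    d <- sum(bitwAnd(bitwShiftR(bitwXor(words[i], words[j]), 0:14), 1))
    expect_gte(d, 5)
  }
})

test_that("text round-trips through QR encode/decode across versions", {
  set.seed(9)
  for (v in c(1, 2, 4, 5, 7, 10)) {
    text <- paste(sample(c(letters, LETTERS, 0:9, ";", ":", " "),
                         min(6 * v, 60), replace = TRUE), collapse = "")
    m <- stegomed:::qr_encode_matrix(text, level = "M", version = v)
    expect_identical(stegomed:::qr_decode_matrix(m), text)
  }
})

test_that("qr bitmaps survive module flips within the EC budget", {
  set.seed(10)
  text <- "Patient: A; ID: 001"
  qr <- text_to_qr(text)
  expect_identical(qr_to_text(qr), text)
  m <- stegomed:::qr_encode_matrix(text, level = "M")
  for (rep in 1:5) {
    m2 <- m
    flip <- sample(length(m2), 6)
    m2[flip] <- 1 - m2[flip]
    expect_identical(stegomed:::qr_decode_matrix(m2), text)
  }
})

test_that("degenerate QR inputs raise capacity or decode errors", {
  expect_error(text_to_qr(""), "capacity")
  expect_error(text_to_qr(strrep("x", 1000)), "capacity")
  expect_error(qr_to_text(qr_bitmap(matrix(0, 84, 84), 4L)), "decode")
  # distinct payloads give distinct symbols
  a <- text_to_qr("ID:41")$bits
  b <- text_to_qr("ID:42")$bits
  expect_false(identical(a, b))
})
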