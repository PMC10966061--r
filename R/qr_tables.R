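# QR model-2 constants for versions 1-10, byte mode.
#
# Error-correction block structure per (version, level): each row of the
# inner matrix is one block group: c(number of blocks, data codewords per
# block); ec codewords per block is constant within a version/level.

qr_gf_exp <- local({
  e <- integer(512)
  x <- 1L
  for (i in 0:254) {
    e[i + 1L] <- x
    x <- bitwShiftL(x, 1L)
    if (x >= 256L) x <- bitwXor(x, 285L)
  }
  e[256:510] <- e[1:255]
  e
})

qr_gf_log <- local({
  l <- integer(256)
  for (i in 0:254) l[qr_gf_exp[i + 1L] + 1L] <- i
  l
})

gf_mul <- function(a, b) {
  out <- integer(length(a) * 0 + max(length(a), length(b)))
  a <- rep_len(a, length(out)); b <- rep_len(b, length(out))
  nz <- a != 0L & b != 0L
  out[nz] <- qr_gf_exp[(qr_gf_log[a[nz] + 1L] + qr_gf_log[b[nz] + 1L]) %% 255L + 1L]
  out
}

gf_inv <- function(a) {
  if (any(a == 0L)) stop("division by zero in GF(256)")
  qr_gf_exp[(255L - qr_gf_log[a + 1L]) %% 255L + 1L]
}

# polynomial ops; coefficients highest degree first
gf_poly_mul <- function(p, q) {
  out <- integer(length(p) + length(q) - 1L)
  for (i in seq_along(p)) {
    if (p[i] == 0L) next
    out[i:(i + length(q) - 1L)] <- bitwXor(out[i:(i + length(q) - 1L)],
                                           gf_mul(p[i], q))
  }
  out
}

gf_poly_eval <- function(p, x) {
  y <- 0L
  for (coef in p) y <- bitwXor(gf_mul(y, x), coef)
  y
}

qr_rs_generator <- function(n_ec) {
  g <- 1L
  for (i in 0:(n_ec - 1L)) g <- gf_poly_mul(g, c(1L, qr_gf_exp[i + 1L]))
  g
}

# Reed-Solomon parity codewords for a data block
qr_rs_encode <- function(data, n_ec) {
  gen <- qr_rs_generator(n_ec)
  buf <- c(as.integer(data), integer(n_ec))
  for (i in seq_along(data)) {
    lead <- buf[i]
    if (lead != 0L) {
      idx <- i:(i + n_ec)
      buf[idx] <- bitwXor(buf[idx], gf_mul(lead, gen))
    }
  }
  buf[(length(data) + 1L):length(buf)]
}

# Berlekamp-Massey + Chien + Forney decoder; returns corrected codeword or
# NULL when the error weight exceeds the correction capacity
qr_rs_decode <- function(received, n_ec) {
  n <- length(received)
  synd <- vapply(0:(n_ec - 1L), function(j) {
    gf_poly_eval(received, qr_gf_exp[j + 1L])
  }, integer(1))
  if (all(synd == 0L)) return(received)

  # Berlekamp-Massey, coefficients lowest degree first
  C <- c(1L, integer(n_ec)); B <- c(1L, integer(n_ec))
  L <- 0L; m <- 1L; b <- 1L
  for (i in seq_len(n_ec)) {
    d <- synd[i]
    if (L > 0L) {
      for (j in seq_len(L)) d <- bitwXor(d, gf_mul(C[j + 1L], synd[i - j]))
    }
    if (d == 0L) {
      m <- m + 1L
    } else if (2L * L <= i - 1L) {
      Tm <- C
      coef <- gf_mul(d, gf_inv(b))
      shifted <- c(integer(m), gf_mul(coef, B[seq_len(length(B) - m)]))
      C <- bitwXor(C, shifted[seq_along(C)])
      L <- i - L; B <- Tm; b <- d; m <- 1L
    } else {
      coef <- gf_mul(d, gf_inv(b))
      shifted <- c(integer(m), gf_mul(coef, B[seq_len(length(B) - m)]))
      C <- bitwXor(C, shifted[seq_along(C)])
      m <- m + 1L
    }
  }
  lambda <- C[1:(L + 1L)]
  if (lambda[1L] != 1L && lambda[1L] != 0L) {
    lambda <- gf_mul(lambda, gf_inv(lambda[1L]))
  }

  # Chien search: error positions i (power of x in the codeword polynomial)
  err_pos <- integer(0)
  for (i in 0:(n - 1L)) {
    xi_inv <- qr_gf_exp[(255L - i) %% 255L + 1L]
    acc <- 0L; xp <- 1L
    for (j in seq_along(lambda)) {
      acc <- bitwXor(acc, gf_mul(lambda[j], xp))
      xp <- gf_mul(xp, xi_inv)
    }
    if (acc == 0L) err_pos <- c(err_pos, i)
  }
  if (length(err_pos) != L) return(NULL)

  # Forney: omega = [S(x) * lambda(x)] mod x^n_ec, lowest degree first
  Spoly <- as.integer(synd)
  omega <- integer(n_ec)
  for (i in seq_along(Spoly)) {
    if (Spoly[i] == 0L) next
    for (j in seq_along(lambda)) {
      k <- i + j - 1L
      if (k <= n_ec) omega[k] <- bitwXor(omega[k], gf_mul(Spoly[i], lambda[j]))
    }
  }
  out <- as.integer(received)
  for (i in err_pos) {
    xi <- qr_gf_exp[i %% 255L + 1L]
    xi_inv <- qr_gf_exp[(255L - i) %% 255L + 1L]
    num <- 0L; xp <- 1L
    for (j in seq_along(omega)) {
      num <- bitwXor(num, gf_mul(omega[j], xp))
      xp <- gf_mul(xp, xi_inv)
    }
    den <- 0L
    # lambda'(x): odd-degree terms only (char 2)
    for (j in seq_along(lambda)) {
      deg <- j - 1L
      if (deg %% 2L == 1L) {
        den <- bitwXor(den, gf_mul(lambda[j],
                                   qr_gf_exp[(qr_gf_log[xi_inv + 1L] * (deg - 1L)) %% 255L + 1L]))
      }
    }
    if (den == 0L) return(NULL)
    mag <- gf_mul(gf_mul(xi, num), gf_inv(den))
    pos <- n - i  # vector index: coefficient of x^i
    out[pos] <- bitwXor(out[pos], mag)
  }
  # verify
  synd2 <- vapply(0:(n_ec - 1L), function(j) gf_poly_eval(out, qr_gf_exp[j + 1L]),
                  integer(1))
  if (any(synd2 != 0L)) return(NULL)
  out
}

# (version, level) -> list(ec_per_block, groups = matrix(nblocks, datacw))
qr_ec_table <- local({
  lv <- function(ec, ...) {
    g <- matrix(c(...), ncol = 2, byrow = TRUE)
    list(ec = ec, groups = g)
  }
  list(
    `1` = list(L = lv(7, 1, 19),  M = lv(10, 1, 16), Q = lv(13, 1, 13), H = lv(17, 1, 9)),
    `2` = list(L = lv(10, 1, 34), M = lv(16, 1, 28), Q = lv(22, 1, 22), H = lv(28, 1, 16)),
    `3` = list(L = lv(15, 1, 55), M = lv(26, 1, 44), Q = lv(18, 2, 17), H = lv(22, 2, 13)),
    `4` = list(L = lv(20, 1, 80), M = lv(18, 2, 32), Q = lv(26, 2, 24), H = lv(16, 4, 9)),
    `5` = list(L = lv(26, 1, 108), M = lv(24, 2, 43), Q = lv(18, 2, 15, 2, 16), H = lv(22, 2, 11, 2, 12)),
    `6` = list(L = lv(18, 2, 68), M = lv(16, 4, 27), Q = lv(24, 4, 19), H = lv(28, 4, 15)),
    `7` = list(L = lv(20, 2, 78), M = lv(18, 4, 31), Q = lv(18, 2, 14, 4, 15), H = lv(26, 4, 13, 1, 14)),
    `8` = list(L = lv(24, 2, 97), M = lv(22, 2, 38, 2, 39), Q = lv(22, 4, 18, 2, 19), H = lv(26, 4, 14, 2, 15)),
    `9` = list(L = lv(30, 2, 116), M = lv(22, 3, 36, 2, 37), Q = lv(20, 4, 16, 4, 17), H = lv(24, 4, 12, 4, 13)),
    `10` = list(L = lv(18, 2, 68, 2, 69), M = lv(26, 4, 43, 1, 44), Q = lv(24, 6, 19, 2, 20), H = lv(28, 6, 15, 2, 16))
  )
})

qr_total_codewords <- c(26L, 44L, 70L, 100L, 134L, 172L, 196L, 242L, 292L, 346L)
qr_remainder_bits <- c(0L, 7L, 7L, 7L, 7L, 7L, 0L, 0L, 0L, 0L)

qr_alignment_centers <- list(
  integer(0), c(6L, 18L), c(6L, 22L), c(6L, 26L), c(6L, 30L),
  c(6L, 34L), c(6L, 22L, 38L), c(6L, 24L, 42L), c(6L, 26L, 46L), c(6L, 28L, 50L)
)

qr_data_capacity <- function(version, level) {
  t <- qr_ec_table[[version]][[level]]
  sum(t$groups[, 1] * t$groups[, 2])
}

# 15-bit format information (5 data bits + BCH(15,5) + fixed XOR mask)
qr_format_bits <- function(level, mask_id) {
  ec_bits <- c(L = 1L, M = 0L, Q = 3L, H = 2L)[[level]]
  data <- bitwOr(bitwShiftL(ec_bits, 3L), mask_id)
  v <- bitwShiftL(data, 10L)
  g <- 1335L  # 0x537
  for (i in 14:10) {
    if (bitwAnd(v, bitwShiftL(1L, i)) != 0L) {
      v <- bitwXor(v, bitwShiftL(g, i - 10L))
    }
  }
  code <- bitwXor(bitwOr(bitwShiftL(data, 10L), v), 21522L)  # 0x5412
  as.integer(bitwAnd(bitwShiftR(code, 14:0), 1L))  # MSB first
}

# 18-bit version information (versions >= 7)
qr_version_bits <- function(version) {
  v <- bitwShiftL(version, 12L)
  g <- 7973L  # 0x1F25
  for (i in 17:12) {
    if (bitwAnd(v, bitwShiftL(1L, i)) != 0L) {
      v <- bitwXor(v, bitwShiftL(g, i - 12L))
    }
  }
  code <- bitwOr(bitwShiftL(version, 12L), v)
  as.integer(bitwAnd(bitwShiftR(code, 17:0), 1L))  # MSB first
}
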