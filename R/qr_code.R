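# QR symbol construction and grid decoding (model 2, byte mode, v1-10).
#
# The decoder operates on an exact module grid (the package embeds and
# recovers bitmaps, it does not locate symbols in photographs); flipped
# modules are handled by the Reed-Solomon layer.

# function-module template: list(modules = matrix, is_function = logical matrix)
qr_template <- function(version) {
  n <- 4L * version + 17L
  mod <- matrix(0L, n, n)
  fun <- matrix(FALSE, n, n)

  place_finder <- function(r0, c0) {
    for (dr in -1:7) for (dc in -1:7) {
      r <- r0 + dr; c <- c0 + dc
      if (r < 1L || r > n || c < 1L || c > n) next
      on <- (dr %in% 0:6 && dc %in% c(0L, 6L)) ||
        (dc %in% 0:6 && dr %in% c(0L, 6L)) ||
        (dr %in% 2:4 && dc %in% 2:4)
      mod[r, c] <<- as.integer(on && dr >= 0 && dr <= 6 && dc >= 0 && dc <= 6)
      fun[r, c] <<- TRUE
    }
  }
  place_finder(1L, 1L)
  place_finder(1L, n - 6L)
  place_finder(n - 6L, 1L)

  # timing patterns
  for (k in 9:(n - 8L)) {
    mod[7L, k] <- as.integer(k %% 2L == 1L); fun[7L, k] <- TRUE
    mod[k, 7L] <- as.integer(k %% 2L == 1L); fun[k, 7L] <- TRUE
  }

  # alignment patterns (skip any overlapping a finder)
  centers <- qr_alignment_centers[[version]]
  cmax <- if (length(centers)) max(centers) else 0L
  for (rc in centers) for (cc in centers) {
    # only the three combinations overlapping finder corners are omitted;
    # patterns crossing the timing lines are placed (and agree with them)
    if ((rc == 6L && cc == 6L) || (rc == 6L && cc == cmax) ||
        (rc == cmax && cc == 6L)) next
    r0 <- rc + 1L; c0 <- cc + 1L
    for (dr in -2:2) for (dc in -2:2) {
      on <- max(abs(dr), abs(dc)) != 1L
      mod[r0 + dr, c0 + dc] <- as.integer(on)
      fun[r0 + dr, c0 + dc] <- TRUE
    }
  }

  # dark module
  mod[4L * version + 10L, 9L] <- 1L
  fun[4L * version + 10L, 9L] <- TRUE

  # reserve format areas
  fmt <- qr_format_positions(n)
  for (p in c(fmt$copy1, fmt$copy2)) fun[p] <- TRUE

  if (version >= 7L) {
    fun[1:6, (n - 10L):(n - 8L)] <- TRUE
    fun[(n - 10L):(n - 8L), 1:6] <- TRUE
  }
  list(modules = mod, is_function = fun, n = n)
}

# linear indices (into an n x n matrix) of the 15 format bits, MSB first
qr_format_positions <- function(n) {
  idx <- function(r, c) (c - 1L) * n + r
  copy1 <- c(idx(9L, 1:6), idx(9L, 8L), idx(9L, 9L), idx(8L, 9L), idx(6:1, 9L))
  copy2 <- c(idx(n:(n - 6L), 9L), idx(9L, (n - 7L):n))
  list(copy1 = copy1, copy2 = copy2)
}

# order in which data bits are laid out (linear indices), standard zigzag
qr_placement_order <- function(tmpl) {
  n <- tmpl$n
  fun <- tmpl$is_function
  order <- integer(0)
  col <- n
  upward <- TRUE
  while (col >= 1L) {
    if (col == 7L) col <- col - 1L  # skip the timing column
    rows <- if (upward) n:1 else 1:n
    for (r in rows) for (c in c(col, col - 1L)) {
      if (c >= 1L && !fun[r, c]) order <- c(order, (c - 1L) * n + r)
    }
    upward <- !upward
    col <- col - 2L
  }
  order
}

qr_mask_matrix <- function(mask_id, n) {
  i <- matrix(0:(n - 1L), n, n)          # row index
  j <- matrix(0:(n - 1L), n, n, byrow = TRUE)
  cond <- switch(as.character(mask_id),
    "0" = (i + j) %% 2L == 0L,
    "1" = i %% 2L == 0L,
    "2" = j %% 3L == 0L,
    "3" = (i + j) %% 3L == 0L,
    "4" = (i %/% 2L + j %/% 3L) %% 2L == 0L,
    "5" = (i * j) %% 2L + (i * j) %% 3L == 0L,
    "6" = ((i * j) %% 2L + (i * j) %% 3L) %% 2L == 0L,
    "7" = ((i + j) %% 2L + (i * j) %% 3L) %% 2L == 0L,
    stop("invalid mask id"))
  cond * 1L
}

qr_penalty <- function(m) {
  n <- nrow(m)
  score <- 0
  runs <- function(v) {
    r <- rle(v)
    sum(ifelse(r$lengths >= 5L, 3L + (r$lengths - 5L), 0L))
  }
  for (k in seq_len(n)) score <- score + runs(m[k, ]) + runs(m[, k])
  blk <- m[-n, -n] + m[-n, -1] + m[-1, -n] + m[-1, -1]
  score <- score + 3L * sum(blk == 0L | blk == 4L)
  pat1 <- c(1, 0, 1, 1, 1, 0, 1, 0, 0, 0, 0)
  pat2 <- rev(pat1)
  findpat <- function(v) {
    if (length(v) < 11L) return(0L)
    s <- 0L
    for (st in 1:(length(v) - 10L)) {
      w <- v[st:(st + 10L)]
      if (all(w == pat1) || all(w == pat2)) s <- s + 40L
    }
    s
  }
  for (k in seq_len(n)) score <- score + findpat(m[k, ]) + findpat(m[, k])
  dark <- mean(m)
  score + 10L * (abs(floor(dark * 100) - 50) %/% 5L)
}

# bytes -> interleaved codeword sequence (data then ec)
qr_interleave <- function(data_cw, version, level) {
  t <- qr_ec_table[[version]][[level]]
  blocks <- list()
  pos <- 1L
  for (g in seq_len(nrow(t$groups))) {
    for (b in seq_len(t$groups[g, 1])) {
      len <- t$groups[g, 2]
      blocks[[length(blocks) + 1L]] <- data_cw[pos:(pos + len - 1L)]
      pos <- pos + len
    }
  }
  ec_blocks <- lapply(blocks, qr_rs_encode, n_ec = t$ec)
  maxd <- max(vapply(blocks, length, integer(1)))
  inter <- integer(0)
  for (i in seq_len(maxd)) {
    for (blk in blocks) if (i <= length(blk)) inter <- c(inter, blk[i])
  }
  for (i in seq_len(t$ec)) {
    for (blk in ec_blocks) inter <- c(inter, blk[i])
  }
  inter
}

qr_deinterleave <- function(cw, version, level) {
  t <- qr_ec_table[[version]][[level]]
  lens <- integer(0)
  for (g in seq_len(nrow(t$groups))) {
    lens <- c(lens, rep(t$groups[g, 2], t$groups[g, 1]))
  }
  nb <- length(lens)
  data_blocks <- lapply(lens, function(l) integer(l))
  pos <- 1L
  for (i in seq_len(max(lens))) {
    for (b in seq_len(nb)) {
      if (i <= lens[b]) {
        data_blocks[[b]][i] <- cw[pos]; pos <- pos + 1L
      }
    }
  }
  ec_blocks <- lapply(seq_len(nb), function(b) integer(t$ec))
  for (i in seq_len(t$ec)) {
    for (b in seq_len(nb)) {
      ec_blocks[[b]][i] <- cw[pos]; pos <- pos + 1L
    }
  }
  list(data = data_blocks, ec = ec_blocks, n_ec = t$ec)
}

# text -> module matrix (0/1, n x n)
qr_encode_matrix <- function(text, level = "M", version = NULL, mask = NULL) {
  bytes <- as.integer(charToRaw(enc2utf8(text)))
  if (length(bytes) == 0L) stop("capacity error: empty payload")
  need_version <- function(v) {
    cci <- if (v <= 9L) 8L else 16L
    bits <- 4L + cci + 8L * length(bytes)
    ceiling(bits / 8L) <= qr_data_capacity(v, level)
  }
  if (is.null(version)) {
    version <- NA_integer_
    for (v in 1:10) if (need_version(v)) { version <- v; break }
    if (is.na(version)) {
      stop("capacity error: payload of ", length(bytes),
           " bytes exceeds version 10-", level, " capacity")
    }
  } else if (!need_version(version)) {
    stop("capacity error: payload does not fit version ", version, "-", level)
  }

  cci <- if (version <= 9L) 8L else 16L
  bits <- c(c(0L, 1L, 0L, 0L),
            as.integer(bitwAnd(bitwShiftR(length(bytes), (cci - 1L):0), 1L)),
            as.integer(vapply(bytes, function(b)
              bitwAnd(bitwShiftR(b, 7:0), 1L), integer(8))))
  cap_bits <- 8L * qr_data_capacity(version, level)
  bits <- c(bits, integer(min(4L, cap_bits - length(bits))))      # terminator
  if (length(bits) %% 8L != 0L) bits <- c(bits, integer(8L - length(bits) %% 8L))
  cw <- vapply(seq_len(length(bits) / 8L), function(i) {
    sum(bits[(8L * i - 7L):(8L * i)] * bitwShiftL(1L, 7:0))
  }, numeric(1))
  pad <- c(236L, 17L)
  while (length(cw) < qr_data_capacity(version, level)) {
    cw <- c(cw, pad[(length(cw) %% 2L) + 1L])
  }

  inter <- qr_interleave(as.integer(cw), version, level)
  stream <- as.integer(unlist(lapply(inter, function(b)
    bitwAnd(bitwShiftR(b, 7:0), 1L))))
  stream <- c(stream, integer(qr_remainder_bits[version]))

  tmpl <- qr_template(version)
  order <- qr_placement_order(tmpl)
  stopifnot(length(order) == length(stream))
  m <- tmpl$modules
  m[order] <- stream

  masks <- if (is.null(mask)) 0:7 else mask
  best <- NULL; best_score <- Inf; best_id <- 0L
  for (k in masks) {
    mm <- qr_mask_matrix(k, tmpl$n)
    cand <- m
    cand[order] <- bitwXor(cand[order], mm[order])
    cand <- qr_apply_format(cand, tmpl, level, k, version)
    sc <- qr_penalty(cand)
    if (sc < best_score) { best <- cand; best_score <- sc; best_id <- k }
  }
  attr(best, "version") <- version
  attr(best, "level") <- level
  attr(best, "mask") <- best_id
  best
}

qr_apply_format <- function(m, tmpl, level, mask_id, version) {
  fb <- qr_format_bits(level, mask_id)
  fmt <- qr_format_positions(tmpl$n)
  m[fmt$copy1] <- fb
  m[fmt$copy2] <- fb
  if (version >= 7L) {
    vb <- rev(qr_version_bits(version))  # vb[i] is bit i-1 (LSB first)
    n <- tmpl$n
    for (i in 0:17) {
      r <- i %/% 3L; c <- i %% 3L
      m[r + 1L, n - 10L + c] <- vb[i + 1L]
      m[n - 10L + c, r + 1L] <- vb[i + 1L]
    }
  }
  m
}

# module matrix -> text; NULL on failure is never returned: errors signal
# undecodable input so callers can distinguish corruption from success
qr_decode_matrix <- function(m) {
  n <- nrow(m)
  if (n != ncol(m) || (n - 17L) %% 4L != 0L) stop("decode error: not a QR module grid")
  version <- (n - 17L) %/% 4L
  if (version < 1L || version > 10L) stop("decode error: unsupported version")
  tmpl <- qr_template(version)
  fmt <- qr_format_positions(n)
  got1 <- m[fmt$copy1]; got2 <- m[fmt$copy2]
  best <- NULL; best_d <- Inf
  for (lv in c("L", "M", "Q", "H")) for (k in 0:7) {
    fb <- qr_format_bits(lv, k)
    d <- sum(fb != got1) + sum(fb != got2)
    if (d < best_d) { best_d <- d; best <- list(level = lv, mask = k) }
  }
  if (best_d > 6) stop("decode error: format information unreadable")
  order <- qr_placement_order(tmpl)
  mm <- qr_mask_matrix(best$mask, n)
  bits <- bitwXor(as.integer(m[order]), as.integer(mm[order]))
  n_cw <- qr_total_codewords[version]
  bits <- bits[seq_len(8L * n_cw)]
  cw <- vapply(seq_len(n_cw), function(i) {
    sum(bits[(8L * i - 7L):(8L * i)] * bitwShiftL(1L, 7:0))
  }, numeric(1))
  blocks <- qr_deinterleave(as.integer(cw), version, best$level)
  data <- integer(0)
  for (b in seq_along(blocks$data)) {
    fixed <- qr_rs_decode(c(blocks$data[[b]], blocks$ec[[b]]), blocks$n_ec)
    if (is.null(fixed)) stop("decode error: error correction failed")
    data <- c(data, fixed[seq_along(blocks$data[[b]])])
  }
  dbits <- as.integer(unlist(lapply(data, function(b) bitwAnd(bitwShiftR(b, 7:0), 1L))))
  mode <- sum(dbits[1:4] * c(8L, 4L, 2L, 1L))
  if (mode != 4L) stop("decode error: unsupported mode ", mode)
  cci <- if (version <= 9L) 8L else 16L
  count <- sum(dbits[5:(4L + cci)] * bitwShiftL(1L, (cci - 1L):0))
  if (4L + cci + 8L * count > length(dbits)) stop("decode error: truncated payload")
  bytes <- vapply(seq_len(count), function(i) {
    st <- 4L + cci + 8L * (i - 1L)
    sum(dbits[(st + 1L):(st + 8L)] * bitwShiftL(1L, 7:0))
  }, numeric(1))
  out <- rawToChar(as.raw(bytes))
  Encoding(out) <- "UTF-8"
  out
}
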