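# Independent structural QR reader used as the decode oracle: rebuilds the
# function-pattern map from the standard's construction, reads the format
# information, unmasks, walks the zigzag placement, deinterleaves the
# codeword blocks, verifies the Reed-Solomon syndromes are all zero, and
# parses the byte-mode payload back to text. Written as its own code path,
# sharing nothing with the encoder under test.

qr_reader_gf <- local({
  exp_t <- integer(512)
  log_t <- integer(256)
  x <- 1L
  for (i in 0:254) {
    exp_t[i + 1] <- x
    log_t[x + 1] <- i
    x <- bitwShiftL(x, 1L)
    if (x >= 256L) x <- bitwXor(x, 285L)
  }
  exp_t[256:510] <- exp_t[1:255]
  list(exp = exp_t, log = log_t)
})

qr_reader_blocks_L <- list(
  list(c(1L, 19L)), list(c(1L, 34L)), list(c(1L, 55L)), list(c(1L, 80L)),
  list(c(1L, 108L)), list(c(2L, 68L)), list(c(2L, 78L)), list(c(2L, 97L)),
  list(c(2L, 116L)), list(c(2L, 68L), c(2L, 69L))
)
qr_reader_ec_L <- c(7L, 10L, 15L, 20L, 26L, 18L, 20L, 24L, 30L, 18L)
qr_reader_align <- list(
  integer(0), c(6L, 18L), c(6L, 22L), c(6L, 26L), c(6L, 30L), c(6L, 34L),
  c(6L, 22L, 38L), c(6L, 24L, 42L), c(6L, 26L, 46L), c(6L, 28L, 50L)
)

# TRUE where a module belongs to a function pattern / reserved area.
qr_reader_function_map <- function(version) {
  size <- 17L + 4L * version
  f <- matrix(FALSE, size, size)
  mark <- function(rows, cols) f[rows, cols] <<- TRUE
  mark(1:8, 1:8)                       # finder + separator, top-left
  mark(1:8, (size - 7):size)           # top-right
  mark((size - 7):size, 1:8)           # bottom-left
  f[7, ] <- TRUE                       # timing row
  f[, 7] <- TRUE                       # timing column
  for (r in qr_reader_align[[version]]) {
    for (c in qr_reader_align[[version]]) {
      # centres falling inside a finder corner carry no alignment pattern
      if ((r <= 8 && c <= 8) || (r <= 8 && c >= size - 9) ||
          (r >= size - 9 && c <= 8)) {
        next
      }
      f[(r - 1):(r + 3), (c - 1):(c + 3)] <- TRUE
    }
  }
  f[9, 1:9] <- TRUE                    # format areas
  f[1:9, 9] <- TRUE
  f[9, (size - 7):size] <- TRUE
  f[(size - 7):size, 9] <- TRUE
  if (version >= 7) {
    f[(size - 10):(size - 8), 1:6] <- TRUE
    f[1:6, (size - 10):(size - 8)] <- TRUE
  }
  f
}

qr_reader_mask_bit <- function(mask, r, c) {
  # r, c 0-indexed
  on <- switch(mask + 1L,
    (r + c) %% 2 == 0,
    r %% 2 == 0,
    c %% 3 == 0,
    (r + c) %% 3 == 0,
    (r %/% 2 + c %/% 3) %% 2 == 0,
    (r * c) %% 2 + (r * c) %% 3 == 0,
    ((r * c) %% 2 + (r * c) %% 3) %% 2 == 0,
    ((r + c) %% 2 + (r * c) %% 3) %% 2 == 0
  )
  as.integer(on)
}

# Decode a clean (error-free) level-L byte-mode QR matrix back to its text.
# Errors out on any structural inconsistency.
qr_reader_decode <- function(m) {
  m <- unclass(m)
  size <- nrow(m)
  version <- (size - 17L) %/% 4L
  stopifnot(size == 17L + 4L * version, version >= 1, version <= 10)

  # format info, first copy; un-XOR and validate the BCH remainder
  fmt_coords <- list(
    c(9, 1), c(9, 2), c(9, 3), c(9, 4), c(9, 5), c(9, 6), c(9, 8), c(9, 9),
    c(8, 9), c(6, 9), c(5, 9), c(4, 9), c(3, 9), c(2, 9), c(1, 9)
  )
  bits <- vapply(fmt_coords, function(rc) m[rc[1], rc[2]], integer(1))
  fmt <- sum(bits * 2^(14:0))
  fmt <- bitwXor(fmt, strtoi("101010000010010", 2L))
  # polynomial division by 10100110111
  v <- fmt
  gen <- strtoi("10100110111", 2L)
  for (shift in 4:0) {
    if (bitwAnd(v, bitwShiftL(1L, 10L + shift)) > 0) {
      v <- bitwXor(v, bitwShiftL(gen, shift))
    }
  }
  if (v != 0) stop("format information fails its BCH check")
  data5 <- bitwShiftR(fmt, 10L)
  ec_bits <- bitwShiftR(data5, 3L)
  if (ec_bits != 1L) stop("not error-correction level L")
  mask <- bitwAnd(data5, 7L)

  fmap <- qr_reader_function_map(version)

  # zigzag walk, collecting unmasked data bits
  bits_out <- integer(0)
  col <- size
  upward <- TRUE
  while (col >= 1) {
    if (col == 7L) col <- col - 1L
    rows <- if (upward) size:1 else 1:size
    for (r in rows) {
      for (cc in c(col, col - 1L)) {
        if (cc >= 1 && !fmap[r, cc]) {
          bit <- bitwXor(m[r, cc], qr_reader_mask_bit(mask, r - 1L, cc - 1L))
          bits_out <- c(bits_out, bit)
        }
      }
    }
    col <- col - 2L
    upward <- !upward
  }

  n_total <- length(bits_out) %/% 8L
  codewords <- vapply(seq_len(n_total), function(i) {
    sum(bits_out[(8L * i - 7L):(8L * i)] * c(128L, 64L, 32L, 16L, 8L, 4L, 2L, 1L))
  }, numeric(1))
  codewords <- as.integer(codewords)

  # deinterleave
  blocks_spec <- qr_reader_blocks_L[[version]]
  n_ec <- qr_reader_ec_L[version]
  lens <- unlist(lapply(blocks_spec, function(g) rep(g[2], g[1])))
  n_blocks <- length(lens)
  data_cw <- codewords[seq_len(sum(lens))]
  ec_cw <- codewords[sum(lens) + seq_len(n_ec * n_blocks)]
  blocks <- lapply(seq_len(n_blocks), function(b) integer(0))
  idx <- 1L
  for (i in seq_len(max(lens))) {
    for (b in seq_len(n_blocks)) {
      if (i <= lens[b]) {
        blocks[[b]] <- c(blocks[[b]], data_cw[idx])
        idx <- idx + 1L
      }
    }
  }
  ecs <- lapply(seq_len(n_blocks), function(b) integer(0))
  idx <- 1L
  for (i in seq_len(n_ec)) {
    for (b in seq_len(n_blocks)) {
      ecs[[b]] <- c(ecs[[b]], ec_cw[idx])
      idx <- idx + 1L
    }
  }

  # Reed-Solomon syndromes of each block must vanish
  gf_mul <- function(a, b) {
    if (a == 0L || b == 0L) return(0L)
    qr_reader_gf$exp[((qr_reader_gf$log[a + 1] + qr_reader_gf$log[b + 1]) %% 255) + 1]
  }
  for (b in seq_len(n_blocks)) {
    poly <- c(blocks[[b]], ecs[[b]])  # highest-degree coefficient first
    for (i in 0:(n_ec - 1)) {
      alpha_i <- qr_reader_gf$exp[i + 1]
      acc <- 0L
      for (coef in poly) acc <- bitwXor(gf_mul(acc, alpha_i), coef)
      if (acc != 0L) stop(sprintf("nonzero RS syndrome in block %d", b))
    }
  }

  # parse the byte-mode segment
  stream <- unlist(lapply(unlist(blocks), function(cw) {
    as.integer(bitwAnd(bitwShiftR(cw, 7:0), 1L))
  }))
  take <- function(n) {
    v <- sum(stream[seq_len(n)] * 2^((n - 1):0))
    stream <<- stream[-seq_len(n)]
    v
  }
  mode <- take(4L)
  if (mode != 4L) stop("not a byte-mode segment")
  len <- take(if (version <= 9) 8L else 16L)
  bytes <- vapply(seq_len(len), function(i) take(8L), numeric(1))
  rawToChar(as.raw(bytes))
}
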