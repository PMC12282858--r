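# QR code generation for share URLs. Byte mode, error-correction level L,
# versions 1-10 (up to 271 payload bytes; longer payloads raise a capacity
# error). Reed-Solomon arithmetic is over GF(256) with the 0x11D primitive
# polynomial; mask selection follows the standard four penalty rules.

QR_DATA_CODEWORDS_L <- c(19L, 34L, 55L, 80L, 108L, 136L, 156L, 194L, 232L, 274L)
QR_EC_PER_BLOCK_L   <- c(7L, 10L, 15L, 20L, 26L, 18L, 20L, 24L, 30L, 18L)
# Block structure at level L: list of (number of blocks, data codewords per
# block); version 10 mixes two block sizes.
QR_BLOCKS_L <- list(
  list(c(1L, 19L)), list(c(1L, 34L)), list(c(1L, 55L)), list(c(1L, 80L)),
  list(c(1L, 108L)), list(c(2L, 68L)), list(c(2L, 78L)), list(c(2L, 97L)),
  list(c(2L, 116L)), list(c(2L, 68L), c(2L, 69L))
)
QR_ALIGNMENT <- list(
  integer(0), c(6L, 18L), c(6L, 22L), c(6L, 26L), c(6L, 30L), c(6L, 34L),
  c(6L, 22L, 38L), c(6L, 24L, 42L), c(6L, 26L, 46L), c(6L, 28L, 50L)
)

# ---- GF(256) ---------------------------------------------------------------

qr_gf_tables <- local({
  exp_t <- integer(512)
  log_t <- integer(256)
  x <- 1L
  for (i in 0:254) {
    exp_t[i + 1] <- x
    log_t[x + 1] <- i
    x <- bitwShiftL(x, 1)
    if (x >= 256L) x <- bitwXor(x, 285L)  # 0x11D
  }
  exp_t[256:510] <- exp_t[1:255]
  list(exp = exp_t, log = log_t)
})

gf_mul <- function(a, b) {
  if (a == 0L || b == 0L) return(0L)
  qr_gf_tables$exp[((qr_gf_tables$log[a + 1] + qr_gf_tables$log[b + 1]) %% 255) + 1]
}

rs_generator <- function(n_ec) {
  g <- 1L
  for (i in 0:(n_ec - 1)) {
    # multiply g by (x - alpha^i)
    alpha_i <- qr_gf_tables$exp[i + 1]
    g_new <- integer(length(g) + 1)
    for (j in seq_along(g)) {
      g_new[j] <- bitwXor(g_new[j], gf_mul(g[j], alpha_i))
      g_new[j + 1] <- bitwXor(g_new[j + 1], g[j])
    }
    g <- g_new
  }
  rev(g)  # highest degree first, monic
}

rs_remainder <- function(data, n_ec) {
  gen <- rs_generator(n_ec)  # length n_ec + 1, gen[1] == 1
  buf <- c(data, integer(n_ec))
  for (i in seq_along(data)) {
    factor <- buf[i]
    if (factor != 0L) {
      for (j in seq_along(gen)) {
        buf[i + j - 1] <- bitwXor(buf[i + j - 1], gf_mul(gen[j], factor))
      }
    }
  }
  utils::tail(buf, n_ec)
}

# ---- BCH codes for format / version info -----------------------------------

bch_remainder <- function(value, n_value_bits, generator, n_rem_bits) {
  v <- bitwShiftL(value, n_rem_bits)
  top <- function(x) {
    b <- 0L
    while (bitwShiftR(x, b + 1) > 0) b <- b + 1L
    b
  }
  gen_top <- top(generator)
  while (v >= bitwShiftL(1L, gen_top)) {
    v <- bitwXor(v, bitwShiftL(generator, top(v) - gen_top))
  }
  v
}

qr_format_bits <- function(mask) {
  # EC level L is encoded as 01.
  data5 <- bitwOr(bitwShiftL(1L, 3), mask)
  rem <- bch_remainder(data5, 5L, 1335L, 10L)       # generator 0b10100110111
  bitwXor(bitwOr(bitwShiftL(data5, 10), rem), 21522L)  # mask 0x5412
}

qr_version_bits <- function(version) {
  rem <- bch_remainder(version, 6L, 7973L, 12L)     # generator 0b1111100100101
  bitwOr(bitwShiftL(version, 12), rem)
}

# ---- matrix construction ----------------------------------------------------

# Returns a list: modules (0/1 matrix) and reserved (function-pattern mask).
qr_function_patterns <- function(version) {
  size <- 17L + 4L * version
  m <- matrix(0L, size, size)
  f <- matrix(FALSE, size, size)

  place_finder <- function(r, c) {
    for (dr in -1:7) for (dc in -1:7) {
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || rr > size || cc < 1 || cc > size) next
      inside <- dr >= 0 && dr <= 6 && dc >= 0 && dc <= 6
      val <- if (!inside) 0L
             else if (dr %in% c(0, 6) || dc %in% c(0, 6)) 1L
             else if (dr >= 2 && dr <= 4 && dc >= 2 && dc <= 4) 1L
             else 0L
      m[rr, cc] <<- val
      f[rr, cc] <<- TRUE
    }
  }
  place_finder(1L, 1L)
  place_finder(1L, size - 6L)
  place_finder(size - 6L, 1L)

  # timing patterns
  for (i in 9:(size - 8)) {
    v <- as.integer(i %% 2 == 1)
    if (!f[7, i]) { m[7, i] <- v; f[7, i] <- TRUE }
    if (!f[i, 7]) { m[i, 7] <- v; f[i, 7] <- TRUE }
  }

  # alignment patterns (centres inside finder corners carry none; centres on
  # the timing lines do, and overwrite them consistently)
  centers <- QR_ALIGNMENT[[version]]
  for (r in centers) for (c in centers) {
    if ((r <= 8 && c <= 8) || (r <= 8 && c >= size - 9) ||
        (r >= size - 9 && c <= 8)) {
      next
    }
    rr <- r + 1L; cc <- c + 1L
    for (dr in -2:2) for (dc in -2:2) {
      val <- if (abs(dr) == 2 || abs(dc) == 2 || (dr == 0 && dc == 0)) 1L else 0L
      m[rr + dr, cc + dc] <- val
      f[rr + dr, cc + dc] <- TRUE
    }
  }

  # reserve format info areas
  for (i in 1:9) { f[9, i] <- TRUE; f[i, 9] <- TRUE }
  for (i in (size - 7):size) { f[9, i] <- TRUE; f[i, 9] <- TRUE }
  # dark module
  m[size - 7L, 9] <- 1L
  f[size - 7L, 9] <- TRUE

  # reserve version info areas
  if (version >= 7) {
    for (i in 0:5) for (j in 0:2) {
      f[size - 10L + j, i + 1L] <- TRUE
      f[i + 1L, size - 10L + j] <- TRUE
    }
  }
  list(modules = m, reserved = f, size = size)
}

# Zigzag order of data module coordinates (row, col), 1-indexed.
qr_data_coords <- function(reserved) {
  size <- nrow(reserved)
  coords <- matrix(0L, nrow = sum(!reserved), ncol = 2)
  idx <- 0L
  col <- size
  upward <- TRUE
  while (col >= 1) {
    if (col == 7L) col <- col - 1L  # skip the timing column
    rows <- if (upward) size:1 else 1:size
    for (r in rows) {
      for (c in c(col, col - 1L)) {
        if (c >= 1 && !reserved[r, c]) {
          idx <- idx + 1L
          coords[idx, ] <- c(r, c)
        }
      }
    }
    col <- col - 2L
    upward <- !upward
  }
  coords[seq_len(idx), , drop = FALSE]
}

qr_mask_value <- function(mask, r, c) {
  # r, c are 0-indexed here, per the standard's formulas.
  switch(mask + 1L,
    (r + c) %% 2 == 0,
    r %% 2 == 0,
    c %% 3 == 0,
    (r + c) %% 3 == 0,
    (r %/% 2 + c %/% 3) %% 2 == 0,
    (r * c) %% 2 + (r * c) %% 3 == 0,
    ((r * c) %% 2 + (r * c) %% 3) %% 2 == 0,
    ((r + c) %% 2 + (r * c) %% 3) %% 2 == 0
  )
}

qr_penalty <- function(m) {
  size <- nrow(m)
  score <- 0L
  runs_penalty <- function(line) {
    r <- rle(line)
    sum(ifelse(r$lengths >= 5, 3L + (r$lengths - 5L), 0L))
  }
  score <- score + sum(vapply(seq_len(size), function(i) {
    runs_penalty(m[i, ]) + runs_penalty(m[, i])
  }, numeric(1)))
  # 2x2 blocks
  blocks <- m[-size, -size] + m[-1, -size] + m[-size, -1] + m[-1, -1]
  score <- score + 3L * sum(blocks == 0 | blocks == 4)
  # finder-like pattern 1011101 with 4 light modules on either side
  pat1 <- c(1, 0, 1, 1, 1, 0, 1, 0, 0, 0, 0)
  pat2 <- rev(pat1)
  count_pat <- function(line) {
    n <- length(line)
    if (n < 11) return(0L)
    hits <- 0L
    for (s in 1:(n - 10)) {
      seg <- line[s:(s + 10)]
      if (all(seg == pat1) || all(seg == pat2)) hits <- hits + 1L
    }
    hits
  }
  score <- score + 40L * sum(vapply(seq_len(size), function(i) {
    count_pat(m[i, ]) + count_pat(m[, i])
  }, numeric(1)))
  dark_pct <- 100 * sum(m) / (size * size)
  score + 10L * (abs(trunc(dark_pct / 5) * 5 - 50) %/% 5)
}

qr_place_format <- function(m, fmt) {
  size <- nrow(m)
  bits <- as.integer(intToBits(fmt))[15:1]  # bits[1] = b14 (MSB) ... bits[15] = b0
  # copy 1, around the top-left finder
  coords1 <- list(
    c(9, 1), c(9, 2), c(9, 3), c(9, 4), c(9, 5), c(9, 6), c(9, 8), c(9, 9),
    c(8, 9), c(6, 9), c(5, 9), c(4, 9), c(3, 9), c(2, 9), c(1, 9)
  )
  # copy 2, split between bottom-left and top-right
  coords2 <- c(
    lapply(0:6, function(i) c(size - i, 9)),
    lapply(7:14, function(i) c(9, size - 14 + i))
  )
  for (i in 1:15) {
    m[coords1[[i]][1], coords1[[i]][2]] <- bits[i]
    m[coords2[[i]][1], coords2[[i]][2]] <- bits[i]
  }
  m
}

qr_place_version <- function(m, version) {
  size <- nrow(m)
  vb <- qr_version_bits(version)
  bits <- as.integer(intToBits(vb))[1:18]  # LSB first
  for (i in 0:17) {
    row <- size - 10L + (i %% 3L)
    col <- i %/% 3L + 1L
    m[row, col] <- bits[i + 1]
    m[col, row] <- bits[i + 1]
  }
  m
}

qr_codewords <- function(payload_bytes, version) {
  n_data <- QR_DATA_CODEWORDS_L[version]
  n_len_bits <- if (version <= 9) 8L else 16L
  bits <- integer(0)
  append_bits <- function(value, n) {
    vb <- integer(n)
    for (i in seq_len(n)) vb[i] <- bitwAnd(bitwShiftR(value, n - i), 1L)
    bits <<- c(bits, vb)
  }
  append_bits(4L, 4L)  # byte mode
  append_bits(length(payload_bytes), n_len_bits)
  for (b in payload_bytes) append_bits(as.integer(b), 8L)
  # terminator + pad to a byte boundary
  bits <- c(bits, integer(min(4L, n_data * 8L - length(bits))))
  if (length(bits) %% 8 != 0) bits <- c(bits, integer(8L - length(bits) %% 8L))
  codewords <- vapply(seq_len(length(bits) / 8), function(i) {
    sum(bits[(8 * i - 7):(8 * i)] * c(128L, 64L, 32L, 16L, 8L, 4L, 2L, 1L))
  }, numeric(1))
  pad <- c(236L, 17L)
  k <- 0L
  while (length(codewords) < n_data) {
    k <- k + 1L
    codewords <- c(codewords, pad[(k - 1L) %% 2L + 1L])
  }
  as.integer(codewords)

}

qr_interleave <- function(codewords, version) {
  n_ec <- QR_EC_PER_BLOCK_L[version]
  blocks <- list()
  pos <- 0L
  for (grp in QR_BLOCKS_L[[version]]) {
    for (b in seq_len(grp[1])) {
      blocks[[length(blocks) + 1]] <- codewords[(pos + 1):(pos + grp[2])]
      pos <- pos + grp[2]
    }
  }
  ec_blocks <- lapply(blocks, rs_remainder, n_ec = n_ec)
  max_len <- max(vapply(blocks, length, integer(1)))
  out <- integer(0)
  for (i in seq_len(max_len)) {
    for (blk in blocks) if (i <= length(blk)) out <- c(out, blk[i])
  }
  for (i in seq_len(n_ec)) {
    for (blk in ec_blocks) out <- c(out, blk[i])
  }
  out
}

#' Encode text as a QR code matrix
#'
#' Byte-mode QR encoding at error-correction level L; the smallest version
#' (1-10) whose capacity fits the text is chosen. Payloads over 271 bytes
#' exceed the supported capacity and raise an error suggesting to reduce the
#' number of shared columns.
#'
#' @param text The text to encode (typically a share URL).
#' @return A `qr_matrix` object: a 0/1 integer matrix (1 = dark) with
#'   attributes `version` and `mask`.
#' @export
qr_matrix <- function(text) {
  stopifnot(is.character(text), length(text) == 1, !is.na(text))
  payload <- charToRaw(enc2utf8(text))
  n_len_bits <- function(v) if (v <= 9) 8L else 16L
  version <- NA_integer_
  for (v in 1:10) {
    capacity_bits <- QR_DATA_CODEWORDS_L[v] * 8L
    if (4L + n_len_bits(v) + 8L * length(payload) <= capacity_bits) {
      version <- v
      break
    }
  }
  if (is.na(version)) {
    abort(glue("payload of {length(payload)} bytes exceeds the QR capacity ",
               "(271 bytes at level L); reduce the number of shared columns"),
          class = "tabreport_capacity_error")
  }

  final <- qr_interleave(qr_codewords(payload, version), version)
  base <- qr_function_patterns(version)
  coords <- qr_data_coords(base$reserved)
  data_bits <- integer(nrow(coords))
  bit_idx <- seq_len(min(nrow(coords), 8L * length(final)))
  all_bits <- as.integer(rawToBits(as.raw(final)))
  # rawToBits is LSB-first per byte; QR wants MSB-first.
  msb_first <- as.vector(t(matrix(all_bits, ncol = 8, byrow = TRUE)[, 8:1]))
  data_bits[bit_idx] <- msb_first[bit_idx]

  best <- NULL
  best_penalty <- Inf
  for (mask in 0:7) {
    m <- base$modules
    masked <- data_bits
    flip <- qr_mask_value(mask, coords[, 1] - 1L, coords[, 2] - 1L)
    masked[flip] <- 1L - masked[flip]
    m[coords] <- masked
    m <- qr_place_format(m, qr_format_bits(mask))
    if (version >= 7) m <- qr_place_version(m, version)
    p <- qr_penalty(m)
    if (p < best_penalty) {
      best_penalty <- p
      best <- structure(m, version = version, mask = mask, class = "qr_matrix")
    }
  }
  best
}

#' Write a QR code image
#'
#' Renders the QR matrix of `text` with a 4-module quiet zone. PNG output
#' uses the `png` package; `.svg` paths get a plain SVG document.
#'
#' @param text Text to encode (typically a share URL).
#' @param path Output file path ending in `.png` or `.svg`.
#' @param scale Pixels per module (PNG only).
#' @return The `qr_matrix`, invisibly.
#' @export
make_qr <- function(text, path, scale = 8L) {
  qm <- qr_matrix(text)
  quiet <- 4L
  size <- nrow(qm) + 2L * quiet
  full <- matrix(0L, size, size)
  full[quiet + seq_len(nrow(qm)), quiet + seq_len(nrow(qm))] <- unclass(qm)
  if (grepl("\\.svg$", path, ignore.case = TRUE)) {
    cells <- which(full == 1L, arr.ind = TRUE)
    rects <- sprintf('<rect x="%d" y="%d" width="1" height="1"/>',
                     cells[, 2] - 1L, cells[, 1] - 1L)
    svg <- paste0(
      '<svg xmlns="http://www.w3.org/2000/svg" viewBox="0 0 ', size, " ",
      size, '" shape-rendering="crispEdges">',
      '<rect width="100%" height="100%" fill="#ffffff"/>',
      '<g fill="#000000">', paste(rects, collapse = ""), "</g></svg>"
    )
    writeLines(svg, path, useBytes = TRUE)
  } else {
    img <- (1 - full)[rep(seq_len(size), each = scale),
                      rep(seq_len(size), each = scale)]
    png::writePNG(img, path)
  }
  invisible(qm)
}

#' @export
print.qr_matrix <- function(x, ...) {
  cat(glue("<qr_matrix> version {attr(x, 'version')}, ",
           "mask {attr(x, 'mask')}, {nrow(x)}x{ncol(x)} modules\n"))
  invisible(x)
}
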