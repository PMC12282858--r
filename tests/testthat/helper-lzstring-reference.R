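# Independent pure-R LZ-string reference implementation, written directly
# from the published algorithm (LZW with literal escape codes 0/1, end code
# 2, growing code width; codes emitted LSB-first, packed MSB-first into
# output characters). Used as the cross-implementation oracle for the
# package's codec: both directions on both alphabets must agree exactly.
# Deliberately naive (named-list dictionaries, character-keyed) and slow;
# only run on short strings.

REF_URI_ALPHABET <- strsplit(
  "ABCDEFGHIJKLMNOPQRSTUVWXYZabcdefghijklmnopqrstuvwxyz0123456789+-$",
  "")[[1]]

ref_utf16_units <- function(text) {
  cps <- utf8ToInt(enc2utf8(text))
  out <- integer(0)
  for (cp in cps) {
    if (cp <= 0xFFFF) {
      out <- c(out, cp)
    } else {
      cp <- cp - 0x10000L
      out <- c(out, 0xD800L + cp %/% 1024L, 0xDC00L + cp %% 1024L)
    }
  }
  out
}

ref_units_to_text <- function(units) {
  cps <- integer(0)
  i <- 1
  while (i <= length(units)) {
    u <- units[i]
    if (u >= 0xD800 && u <= 0xDBFF && i < length(units) &&
        units[i + 1] >= 0xDC00 && units[i + 1] <= 0xDFFF) {
      cps <- c(cps, 0x10000L + (u - 0xD800L) * 1024L + (units[i + 1] - 0xDC00L))
      i <- i + 2
    } else {
      cps <- c(cps, u)
      i <- i + 1
    }
  }
  if (length(cps) == 0) "" else intToUtf8(cps)
}

# Core compressor over UTF-16 code units; returns packed integer characters.
ref_lz_compress_core <- function(units, bits_per_char) {
  data <- integer(0)
  val <- 0L
  pos <- 0L
  write_bits <- function(value, n) {
    for (i in seq_len(n)) {
      val <<- bitwOr(bitwShiftL(val, 1L), bitwAnd(value, 1L))
      if (pos == bits_per_char - 1L) {
        pos <<- 0L
        data <<- c(data, val)
        val <<- 0L
      } else {
        pos <<- pos + 1L
      }
      value <- bitwShiftR(value, 1L)
    }
  }

  num_bits <- 2L
  if (length(units) > 0) {
    dict <- list()
    to_create <- list()
    dict_size <- 3L
    enlarge <- 2L
    w <- character(0)  # sequence of unit strings
    wkey <- function(x) paste(x, collapse = " ")
    emit_w <- function() {
      k <- wkey(w)
      if (!is.null(to_create[[k]])) {
        first <- as.integer(w[1])
        if (first < 256L) {
          write_bits(0L, num_bits)
          write_bits(first, 8L)
        } else {
          write_bits(1L, num_bits)
          write_bits(first, 16L)
        }
        enlarge <<- enlarge - 1L
        if (enlarge == 0L) {
          enlarge <<- bitwShiftL(1L, num_bits)
          num_bits <<- num_bits + 1L
        }
        to_create[[k]] <<- NULL
      } else {
        write_bits(dict[[k]], num_bits)
      }
      enlarge <<- enlarge - 1L
      if (enlarge == 0L) {
        enlarge <<- bitwShiftL(1L, num_bits)
        num_bits <<- num_bits + 1L
      }
    }

    for (u in as.character(units)) {
      if (is.null(dict[[u]])) {
        dict[[u]] <- dict_size
        dict_size <- dict_size + 1L
        to_create[[u]] <- TRUE
      }
      wc <- c(w, u)
      wck <- wkey(wc)
      if (!is.null(dict[[wck]])) {
        w <- wc
      } else {
        emit_w()
        dict[[wck]] <- dict_size
        dict_size <- dict_size + 1L
        w <- u
      }
    }
    if (length(w) > 0) emit_w()
    write_bits(2L, num_bits)
  } else {
    write_bits(2L, 2L)
  }
  while (TRUE) {
    val <- bitwShiftL(val, 1L)
    if (pos == bits_per_char - 1L) {
      data <- c(data, val)
      break
    }
    pos <- pos + 1L
  }
  data
}

ref_lz_decompress_core <- function(chars, reset_value) {
  if (length(chars) == 0) return(integer(0))
  dictionary <- list(integer(0), integer(0), integer(0))
  enlarge <- 4L
  dict_size <- 4L
  num_bits <- 3L
  val <- chars[1]
  position <- reset_value
  index <- 2L
  read_bits <- function(n) {
    bits <- 0L
    power <- 1L
    for (i in seq_len(n)) {
      resb <- bitwAnd(val, position)
      position <<- bitwShiftR(position, 1L)
      if (position == 0L) {
        position <<- reset_value
        val <<- if (index <= length(chars)) chars[index] else 0L
        index <<- index + 1L
      }
      if (resb > 0) bits <- bits + power
      power <- bitwShiftL(power, 1L)
    }
    bits
  }

  first <- read_bits(2L)
  c0 <- switch(first + 1L, read_bits(8L), read_bits(16L), return(integer(0)))
  dictionary[[4]] <- c0
  w <- c0
  result <- c0
  repeat {
    if (index > length(chars) + 1L) stop("corrupt reference stream")
    code <- read_bits(num_bits)
    if (code == 0L || code == 1L) {
      dictionary[[dict_size + 1L]] <- read_bits(if (code == 0L) 8L else 16L)
      dict_size <- dict_size + 1L
      code <- dict_size - 1L
      enlarge <- enlarge - 1L
    } else if (code == 2L) {
      return(result)
    }
    if (enlarge == 0L) {
      enlarge <- bitwShiftL(1L, num_bits)
      num_bits <- num_bits + 1L
    }
    if (code + 1L <= length(dictionary) && length(dictionary[[code + 1L]]) > 0) {
      entry <- dictionary[[code + 1L]]
    } else if (code == dict_size) {
      entry <- c(w, w[1])
    } else {
      stop("corrupt reference stream")
    }
    result <- c(result, entry)
    dictionary[[dict_size + 1L]] <- c(w, entry[1])
    dict_size <- dict_size + 1L
    enlarge <- enlarge - 1L
    w <- entry
    if (enlarge == 0L) {
      enlarge <- bitwShiftL(1L, num_bits)
      num_bits <- num_bits + 1L
    }
  }
}

ref_lz_compress_utf16 <- function(text) {
  packed <- ref_lz_compress_core(ref_utf16_units(text), 15L)
  paste0(ref_units_to_text(packed + 32L), " ")
}

ref_lz_decompress_utf16 <- function(payload) {
  units <- ref_utf16_units(payload) - 32L
  ref_units_to_text(ref_lz_decompress_core(units, 16384L))
}

ref_lz_compress_uri <- function(text) {
  packed <- ref_lz_compress_core(ref_utf16_units(text), 6L)
  paste(REF_URI_ALPHABET[packed + 1L], collapse = "")
}

ref_lz_decompress_uri <- function(payload) {
  chars <- strsplit(chartr(" ", "+", payload), "")[[1]]
  codes <- match(chars, REF_URI_ALPHABET) - 1L
  ref_units_to_text(ref_lz_decompress_core(codes, 32L))
}
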