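# Two-bits-to-one-base (TBOB) information-storage codec.
#
# Each byte is split MSB-first into four 2-bit words and each word maps to a
# single base; the default map sends 00, 01, 10, 11 to G, T, C, A. The codec
# is byte-oriented and text-encoding-agnostic: any text layer (ASCII, UTF-16)
# is the caller's concern, apart from the bundled demonstration message.

#' Two-bit-word to base map
#'
#' Constructs the bijection between the four 2-bit words (`00`, `01`, `10`,
#' `11`) and the four DNA bases used by the storage codec.
#'
#' @param bases Four distinct bases assigned, in order, to the words
#'   `00`, `01`, `10`, `11`. May be given as a single 4-character string
#'   (e.g. `"GTCA"`, the default) or a length-4 character vector.
#'
#' @return A named character vector of class `"base_map"`: names are the
#'   2-bit words, values the bases.
#' @examples
#' base_map()          # 00->G, 01->T, 10->C, 11->A
#' base_map("ACGT")    # an alternative bijection
#' @export
base_map <- function(bases = "GTCA") {
  if (is.character(bases) && length(bases) == 1L && nchar(bases) == 4L) {
    bases <- seq_chars(bases)
  }
  if (length(bases) != 4L || !all(bases %in% DNA_BASES) || anyDuplicated(bases)) {
    stop("'bases' must assign the four distinct bases A, C, G, T to the ",
         "words 00, 01, 10, 11", call. = FALSE)
  }
  structure(setNames(as.character(bases), c("00", "01", "10", "11")),
            class = "base_map")
}

#' @noRd
as_base_map <- function(map) {
  if (inherits(map, "base_map")) return(map)
  base_map(map)
}

# Accept bits as an integer/numeric 0-1 vector or as a "0101" string.
#' @noRd
as_bits <- function(bits) {
  if (is.character(bits)) {
    if (length(bits) != 1L) stop("bit strings must be length 1", call. = FALSE)
    if (nchar(bits) == 0L) return(integer(0))
    bits <- seq_chars(bits)
    if (!all(bits %in% c("0", "1"))) {
      stop("bit string may contain only '0' and '1'", call. = FALSE)
    }
    return(as.integer(bits))
  }
  bits <- as.integer(bits)
  if (length(bits) && !all(bits %in% c(0L, 1L))) {
    stop("bits must all be 0 or 1", call. = FALSE)
  }
  bits
}

#' Convert a bit vector to DNA
#'
#' Non-overlapping 2-bit words (most significant bit first, left to right)
#' are mapped to bases in 5'->3' order.
#'
#' @param bits Bits as an integer vector of 0/1 or a single `"0101..."`
#'   string; the length must be even.
#' @param map A [base_map()].
#' @return A single DNA string of length `length(bits)/2`.
#' @examples
#' bits_to_dna("01010100")  # "TTTG"
#' @export
bits_to_dna <- function(bits, map = base_map()) {
  bits <- as_bits(bits)
  map <- as_base_map(map)
  if (length(bits) %% 2L != 0L) {
    stop("bit vector has odd length (", length(bits),
         "); two bits encode one base", call. = FALSE)
  }
  if (length(bits) == 0L) return("")
  words <- paste0(bits[c(TRUE, FALSE)], bits[c(FALSE, TRUE)])
  paste0(unname(map[words]), collapse = "")
}

#' Convert DNA to a bit vector
#'
#' Inverse of [bits_to_dna()]: each base becomes its 2-bit word, MSB first.
#'
#' @param seq A DNA string over A/C/G/T.
#' @inheritParams bits_to_dna
#' @return An integer vector of 0/1 of length `2 * nchar(seq)`.
#' @examples
#' dna_to_bits("TCAC")  # 0 1 1 0 1 1 1 0
#' @export
dna_to_bits <- function(seq, map = base_map()) {
  assert_dna(seq, "seq")
  map <- as_base_map(map)
  if (nchar(seq) == 0L) return(integer(0))
  inv <- setNames(names(map), map)
  as_bits(paste0(inv[seq_chars(seq)], collapse = ""))
}

#' Pack bits into bytes / unpack bytes into bits
#'
#' Bytes are framed as eight bits, most significant bit first. The two
#' functions are mutual inverses.
#'
#' @param bits Bits (0/1 vector or string); length must be a multiple of 8
#'   for `bits_to_bytes()`.
#' @param bytes A raw vector, or an integer vector with values in 0-255.
#' @return `bits_to_bytes()` returns a raw vector; `bytes_to_bits()` an
#'   integer 0/1 vector of length `8 * length(bytes)`.
#' @examples
#' bits_to_bytes("01010100")        # 54 = 0x54 = ASCII "T"
#' bytes_to_bits(as.raw(84))
#' @export
bits_to_bytes <- function(bits) {
  bits <- as_bits(bits)
  if (length(bits) %% 8L != 0L) {
    stop("bit vector length (", length(bits),
         ") is not a multiple of 8", call. = FALSE)
  }
  if (length(bits) == 0L) return(raw(0))
  mat <- matrix(bits, nrow = 8L)
  as.raw(colSums(mat * 2L^(7:0)))
}

#' @rdname bits_to_bytes
#' @export
bytes_to_bits <- function(bytes) {
  bytes <- as_byte_vector(bytes)
  if (length(bytes) == 0L) return(integer(0))
  # vapply gives an 8 x n matrix (one byte per column, MSB at the top);
  # column-major flattening yields the bytes' bits in order
  as.integer(vapply(as.integer(bytes), function(b) {
    as.integer(bitwAnd(bitwShiftR(b, 7:0), 1L))
  }, integer(8L)))
}

#' @noRd
as_byte_vector <- function(bytes) {
  if (is.raw(bytes)) return(bytes)
  if (is.numeric(bytes)) {
    if (length(bytes) && (any(is.na(bytes)) || any(bytes < 0) || any(bytes > 255) ||
                          any(bytes != floor(bytes)))) {
      stop("byte values must be integers in [0, 255]", call. = FALSE)
    }
    return(as.raw(bytes))
  }
  stop("bytes must be a raw or integer vector", call. = FALSE)
}

#' Encode a byte message as DNA / decode DNA back to bytes
#'
#' `encode_message()` composes [bytes_to_bits()] and [bits_to_dna()]: four
#' bases per byte. `decode_message()` is its inverse and requires the
#' sequence length to be a multiple of 4 (whole bytes). Ambiguity codes
#' (e.g. `N` from a tied consensus) are rejected, not guessed.
#'
#' @param msg A raw vector (or integer vector in 0-255).
#' @param seq A DNA string over A/C/G/T with `nchar(seq) %% 4 == 0`.
#' @inheritParams bits_to_dna
#' @return `encode_message()` a DNA string; `decode_message()` a raw vector.
#' @examples
#' encode_message(charToRaw("T"))   # "TTTG"
#' rawToChar(decode_message("TTTG"))
#' @export
encode_message <- function(msg, map = base_map()) {
  bits_to_dna(bytes_to_bits(msg), map)
}

#' @rdname encode_message
#' @export
decode_message <- function(seq, map = base_map()) {
  assert_dna(seq, "seq")
  if (nchar(seq) %% 4L != 0L) {
    stop("sequence length (", nchar(seq),
         ") is not a multiple of 4; cannot frame whole bytes", call. = FALSE)
  }
  bits_to_bytes(dna_to_bits(seq, map))
}

#' The bundled 60-nt storage fragment and its 15-byte message
#'
#' `storage_fragment()` returns the 60-nt DNA fragment used in the
#' information-storage demonstration. `stored_message_bytes()` returns the
#' 15-byte message it encodes: the name of Tan Kah Kee as three CJK
#' characters in UTF-16 big-endian (two bytes each) followed by nine ASCII
#' letters. `stored_message_text()` renders the two text fields.
#'
#' @return `storage_fragment()` a 60-character DNA string;
#'   `stored_message_bytes()` a raw vector of length 15;
#'   `stored_message_text()` a named character vector with elements
#'   `cjk` and `ascii`.
#' @examples
#' identical(encode_message(stored_message_bytes()), storage_fragment())
#' @export
storage_fragment <- function() {
  "CTTCTGCGTTTCGGCTTTACCTCCTTTGTCGTTCACTGCATCGTTCCGTGCATCTTTCTT"
}

#' @rdname storage_fragment
#' @export
stored_message_bytes <- function() {
  cjk <- iconv("\u9648\u5609\u5e9a", from = "UTF-8", to = "UTF-16BE",
               toRaw = TRUE)[[1L]]
  c(cjk, charToRaw("TanKahKee"))
}

#' @rdname storage_fragment
#' @export
stored_message_text <- function() {
  bytes <- stored_message_bytes()
  c(cjk = iconv(list(bytes[1:6]), from = "UTF-16BE", to = "UTF-8"),
    ascii = rawToChar(bytes[7:15]))
}

#' Read or write a DNA payload as plain text or single-record FASTA
#'
#' @param path File path. Files ending in `.fa`/`.fasta` are handled as
#'   single-record FASTA via Biostrings; anything else as a bare sequence
#'   line.
#' @param seq DNA string to write.
#' @param name FASTA record name used when writing.
#' @return `read_payload_file()` a DNA string; `write_payload_file()` the
#'   path, invisibly.
#' @export
read_payload_file <- function(path) {
  if (grepl("\\.(fa|fasta)$", path, ignore.case = TRUE)) {
    set <- Biostrings::readDNAStringSet(path)
    if (length(set) != 1L) stop("expected a single FASTA record", call. = FALSE)
    return(as.character(set[[1L]]))
  }
  seq <- trimws(readLines(path, warn = FALSE))
  paste0(seq[nzchar(seq)], collapse = "")
}

#' @rdname read_payload_file
#' @export
write_payload_file <- function(seq, path, name = "payload") {
  assert_dna(seq, "seq")
  if (grepl("\\.(fa|fasta)$", path, ignore.case = TRUE)) {
    set <- Biostrings::DNAStringSet(setNames(seq, name))
    Biostrings::writeXStringSet(set, path)
  } else {
    writeLines(seq, path)
  }
  invisible(path)
}
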