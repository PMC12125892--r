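# K-mer codec: fixed-width integer codes for DNA (2 bits/base, k <= 64) and
# protein (5 bits/residue, k <= 25) k-mers, the Prefix/Infix/Suffix split used
# by the disk engine, and record packing with the genome ID in the 8 least
# significant bits.
#
# Codes are carried as per-symbol digit vectors (base 4 or base 32) so that
# k-mers whose codes exceed 2^53 remain exact; a numeric `value` is attached
# whenever it is exactly representable in a double.

DNA_ALPHABET <- c("A", "C", "G", "T")
# 20 standard residues in alphabetical order, then ambiguity/special symbols.
PROTEIN_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                      "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y",
                      "B", "Z", "X", "U", "O")
KMAX_DNA <- 64L
KMAX_PROTEIN <- 25L
PREFIX_BASES <- 5L   # first 5 symbols = first 10 bits of a DNA code

alphabet_symbols <- function(alphabet) {
  switch(alphabet,
         dna = DNA_ALPHABET,
         protein = PROTEIN_ALPHABET,
         usage_error(sprintf("unknown alphabet '%s'", alphabet)))
}

bits_per_symbol <- function(alphabet) if (alphabet == "dna") 2L else 5L

kmax <- function(alphabet) if (alphabet == "dna") KMAX_DNA else KMAX_PROTEIN

check_k <- function(k, alphabet) {
  if (length(k) != 1L || is.na(k) || k < 1L || k != floor(k)) {
    usage_error("k must be a positive integer")
  }
  if (k > kmax(alphabet)) {
    usage_error(sprintf("k = %d exceeds the maximum of %d for %s alignments",
                        as.integer(k), kmax(alphabet), alphabet))
  }
  as.integer(k)
}

# Internal sort alphabet: symbol with code v maps to LETTERS[v+1], so plain
# character sorting of translated strings equals code order for both
# alphabets (protein code order is not ASCII order).
codec_sortkey <- function(x, alphabet) {
  syms <- alphabet_symbols(alphabet)
  chartr(paste0(syms, collapse = ""),
         paste0(LETTERS[seq_along(syms)], collapse = ""), x)
}

new_kmer_code <- function(digits, alphabet) {
  base <- 2^bits_per_symbol(alphabet)
  nbits <- length(digits) * bits_per_symbol(alphabet)
  value <- if (nbits <= 52L) sum(digits * base^(rev(seq_along(digits)) - 1))
           else NA_real_
  structure(list(digits = as.integer(digits), k = length(digits),
                 alphabet = alphabet, value = value),
            class = "kmer_code")
}

#' @export
print.kmer_code <- function(x, ...) {
  cat(sprintf("<kmer_code %s k=%d%s: %s>\n", x$alphabet, x$k,
              if (is.na(x$value)) "" else sprintf(" value=%.0f", x$value),
              decode_kmer(x)))
  invisible(x)
}

# digit vector for one k-mer string, or NULL if any symbol is outside the
# alphabet (the window then contributes no count)
kmer_digits <- function(kmer, alphabet) {
  chars <- strsplit(kmer, "", fixed = TRUE)[[1]]
  if (alphabet == "dna") chars[chars == "U"] <- "T"
  d <- match(chars, alphabet_symbols(alphabet)) - 1L
  if (anyNA(d)) NULL else d
}

#' Encode a DNA/RNA k-mer as a 2-bit-per-base code
#'
#' Bases map A,C,G,T to 0,1,2,3 (U is treated as T); the leftmost base
#' occupies the most significant bit pair, so code order equals lexicographic
#' order. Any other symbol (N, IUPAC ambiguity codes, ...) rejects the k-mer.
#'
#' @param kmer A single string, 1--64 characters.
#' @return A `kmer_code`, or `NULL` when the k-mer contains a symbol outside
#'   `{A,C,G,T,U}`. The `value` element is the numeric code when it fits a
#'   double exactly (k <= 26), `NA` otherwise (the digit vector is always
#'   exact).
#' @examples
#' encode_dna("ACGT")$value   # 27
#' is.null(encode_dna("ACNGT"))
#' @export
encode_dna <- function(kmer) {
  check_k(nchar(kmer), "dna")
  d <- kmer_digits(toupper(kmer), "dna")
  if (is.null(d)) return(NULL)
  new_kmer_code(d, "dna")
}

#' Encode a protein k-mer as a 5-bit-per-residue code
#'
#' Uses a fixed 25-symbol alphabet (20 standard residues alphabetically, then
#' B, Z, X, U, O) mapped to 0--24. Symbols outside the alphabet, including
#' `*`, reject the k-mer.
#'
#' @param kmer A single string, 1--25 characters.
#' @return A `kmer_code` or `NULL` (symbol outside the alphabet).
#' @examples
#' encode_protein("ACD")$value   # 34
#' @export
encode_protein <- function(kmer) {
  check_k(nchar(kmer), "protein")
  d <- kmer_digits(toupper(kmer), "protein")
  if (is.null(d)) return(NULL)
  new_kmer_code(d, "protein")
}

#' Decode a k-mer code back to its string
#'
#' Inverse of [encode_dna()] / [encode_protein()]: `decode_kmer(encode_dna(s))`
#' is `s` for every unambiguous `s`.
#'
#' @param code A `kmer_code`, or a numeric code value (with `k` and
#'   `alphabet` supplied).
#' @param k,alphabet Used only when `code` is numeric.
#' @return The k-mer string.
#' @examples
#' decode_kmer(27, k = 4)   # "ACGT"
#' @export
decode_kmer <- function(code, k = NULL, alphabet = "dna") {
  if (is.numeric(code)) {
    if (is.null(k)) usage_error("k is required to decode a numeric code")
    k <- check_k(k, alphabet)
    base <- 2^bits_per_symbol(alphabet)
    if (code >= base^k || code < 0) usage_error("code value out of range for k")
    d <- integer(k)
    v <- code
    for (i in k:1) {
      d[i] <- v %% base
      v <- v %/% base
    }
    code <- new_kmer_code(d, alphabet)
  }
  paste0(alphabet_symbols(code$alphabet)[code$digits + 1L], collapse = "")
}

#' @rdname decode_kmer
#' @export
decode_dna <- function(code, k = NULL) decode_kmer(code, k, "dna")

#' Split a DNA k-mer code into Prefix, Infix and Suffix
#'
#' For `k > 10`, the first 10 bits (5 bases) are the Prefix — the disk
#' engine's bin number — the next 10 bits the Infix (partial-sort key), and
#' the remaining `2(k-10)` bits the Suffix. Concatenating the three parts
#' reproduces the original code.
#'
#' @param code A DNA `kmer_code` with `k > 10`.
#' @return A list with integer `prefix` and `infix` (each in `[0, 1023]`),
#'   numeric `suffix` (`NA` when wider than 52 bits), and the exact
#'   `suffix_digits` base-4 digit vector.
#' @examples
#' split_parts(encode_dna("AAAAACCCCCGT"))   # prefix 0, infix 341, suffix 11
#' @export
split_parts <- function(code) {
  if (!inherits(code, "kmer_code") || code$alphabet != "dna") {
    usage_error("split_parts() requires a DNA kmer_code")
  }
  if (code$k <= 2L * PREFIX_BASES) {
    usage_error(sprintf(
      "prefix/infix/suffix split is defined only for k > 10 (got k = %d)",
      code$k))
  }
  d <- code$digits
  prefix <- sum(d[1:5] * 4^(4:0))
  infix <- sum(d[6:10] * 4^(4:0))
  sd <- d[-(1:10)]
  suffix <- if (length(sd) * 2L <= 52L) sum(sd * 4^(rev(seq_along(sd)) - 1))
            else NA_real_
  list(prefix = as.integer(prefix), infix = as.integer(infix),
       suffix = suffix, suffix_digits = sd)
}

#' Reassemble a DNA code from its Prefix and remainder digits
#'
#' @param prefix Integer in `[0, 1023]`.
#' @param remainder_digits Base-4 digits of the infix-plus-suffix remainder.
#' @return A `kmer_code`.
#' @export
assemble_code <- function(prefix, remainder_digits) {
  pd <- integer(PREFIX_BASES)
  v <- prefix
  for (i in PREFIX_BASES:1) {
    pd[i] <- v %% 4L
    v <- v %/% 4L
  }
  new_kmer_code(c(pd, remainder_digits), "dna")
}

#' Pack a (remainder, genome ID, count) triple into a keyed record
#'
#' The packed key places the genome ID in the 8 least significant bits and
#' the k-mer remainder above it: `key = remainder * 256 + genome_id`. The
#' count travels alongside as a separate fixed-width field. This numeric form
#' is exact for remainders below 2^45; the on-disk database uses the
#' equivalent raw-byte packing for arbitrary widths.
#'
#' @param remainder Non-negative remainder value.
#' @param genome_id Integer in `[0, 255]`.
#' @param count Positive count.
#' @return A list with `key` and `count`.
#' @examples
#' pack_record(11, 2, 1)$key   # 2818
#' @export
pack_record <- function(remainder, genome_id, count) {
  if (genome_id < 0 || genome_id >= 256) {
    capacity_error(sprintf("genome_id %d does not fit the 8-bit field",
                           genome_id))
  }
  if (remainder < 0 || remainder > 2^45) {
    usage_error("numeric pack_record() supports remainders up to 2^45")
  }
  list(key = remainder * 256 + genome_id, count = count)
}

#' @rdname pack_record
#' @param key,count Packed key and count, as produced by [pack_record()].
#' @return `unpack_record()`: a list with `remainder`, `genome_id`, `count`.
#' @export
unpack_record <- function(key, count) {
  gid <- key %% 256
  list(remainder = (key - gid) / 256, genome_id = as.integer(gid),
       count = count)
}

## ---- raw-byte record packing (used by the binary database) ----------------
## A stored key is ceil((bps*n_sym + 8)/8) bytes, little-endian; bit layout
## from the least significant end: [8-bit genome id][symbol digits, last
## symbol lowest][zero padding]. Counts are separate 4-byte little-endian
## unsigned integers.

key_width_bytes <- function(n_sym, alphabet) {
  as.integer(ceiling((bits_per_symbol(alphabet) * n_sym + 8L) / 8L))
}

# Vectorized packing: `rems` character vector of equal-length remainder (or
# full k-mer) strings, `gids` integer vector. Returns one raw vector of
# n * (key_width + 4) bytes, records concatenated in input order.
pack_records_raw <- function(rems, gids, counts, alphabet) {
  n <- length(rems)
  if (n == 0L) return(raw(0))
  n_sym <- nchar(rems[1L])
  bps <- bits_per_symbol(alphabet)
  kw <- key_width_bytes(n_sym, alphabet)
  syms <- alphabet_symbols(alphabet)
  # digits matrix: n x n_sym
  ch <- matrix(unlist(strsplit(rems, "", fixed = TRUE), use.names = FALSE),
               nrow = n, byrow = TRUE)
  dig <- matrix(match(ch, syms) - 1L, nrow = n)
  if (anyNA(dig)) {
    usage_error("cannot pack a k-mer containing symbols outside the alphabet")
  }
  # bit matrix, most significant bit first, width kw*8
  nbits <- kw * 8L
  bits <- matrix(0L, nrow = n, ncol = nbits)
  # genome id occupies the last 8 bit columns
  for (b in 0:7) bits[, nbits - b] <- (gids %/% 2^b) %% 2L
  # symbols above it, last symbol lowest
  for (j in seq_len(n_sym)) {
    d <- dig[, n_sym - j + 1L]
    for (b in 0:(bps - 1L)) {
      bits[, nbits - 8L - (j - 1L) * bps - b] <- (d %/% 2^b) %% 2L
    }
  }
  # byte values; column i of `bytes` is the i-th least significant byte
  w <- 2^(7:0)
  bytes <- matrix(0L, nrow = n, ncol = kw + 4L)
  for (i in seq_len(kw)) {
    seg <- bits[, (kw - i) * 8L + 1:8, drop = FALSE]
    bytes[, i] <- as.integer(seg %*% w)
  }
  for (b in 0:3) bytes[, kw + 1L + b] <- (counts %/% 2^(8 * b)) %% 256
  as.raw(t(bytes))
}

# Inverse: raw vector of n records -> list(rems, gids, counts). `n_sym` is the
# number of symbols stored per key.
unpack_records_raw <- function(r, n_sym, alphabet) {
  bps <- bits_per_symbol(alphabet)
  kw <- key_width_bytes(n_sym, alphabet)
  rw <- kw + 4L
  n <- length(r) %/% rw
  if (n * rw != length(r)) {
    format_error("record section length is not a multiple of the record width")
  }
  if (n == 0L) {
    return(list(rems = character(0), gids = integer(0), counts = numeric(0)))
  }
  bytes <- matrix(as.integer(r), nrow = n, ncol = rw, byrow = TRUE)
  gids <- bytes[, 1L]
  counts <- bytes[, kw + 1L] + 256 * bytes[, kw + 2L] +
    65536 * bytes[, kw + 3L] + 16777216 * bytes[, kw + 4L]
  # rebuild the key bit matrix (most significant first)
  nbits <- kw * 8L
  bits <- matrix(0L, nrow = n, ncol = nbits)
  for (i in seq_len(kw)) {
    byte <- bytes[, i]
    for (b in 0:7) bits[, (kw - i) * 8L + (8L - b)] <- (byte %/% 2^b) %% 2L
  }
  syms <- alphabet_symbols(alphabet)
  chm <- matrix("", nrow = n, ncol = n_sym)
  for (j in seq_len(n_sym)) {
    # symbol j (from the left) sits just above the lower (n_sym-j)*bps + 8 bits
    lowbits <- (n_sym - j) * bps + 8L
    cols <- nbits - lowbits - (bps:1) + 1L
    d <- as.integer(bits[, cols, drop = FALSE] %*% 2^((bps - 1L):0))
    chm[, j] <- syms[d + 1L]
  }
  rems <- do.call(paste0, as.data.frame(chm, stringsAsFactors = FALSE))
  list(rems = rems, gids = gids, counts = counts)
}

# Prefix (bin number) of each k-mer string, vectorized; k > 10 DNA only.
kmer_prefix_int <- function(kmers) {
  p5 <- substr(kmers, 1L, PREFIX_BASES)
  ch <- matrix(unlist(strsplit(p5, "", fixed = TRUE), use.names = FALSE),
               ncol = PREFIX_BASES, byrow = TRUE)
  dig <- matrix(match(ch, DNA_ALPHABET) - 1L, ncol = PREFIX_BASES)
  as.integer(dig %*% 4^(4:0))
}

# Inverse: bin number -> 5-base prefix string.
prefix_int_to_string <- function(prefix) {
  out <- character(length(prefix))
  for (i in seq_along(prefix)) {
    v <- prefix[i]
    d <- integer(PREFIX_BASES)
    for (j in PREFIX_BASES:1) {
      d[j] <- v %% 4L
      v <- v %/% 4L
    }
    out[i] <- paste0(DNA_ALPHABET[d + 1L], collapse = "")
  }
  out
}
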