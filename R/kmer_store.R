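# Binary k-mer database.
#
# Layout (all integers little-endian):
#
# <path>.mkc            data file
#   bytes 0..3   magic "MKC1"
#   byte  4      format version (1)
#   byte  5      alphabet tag: 0 = dna, 1 = protein
#   byte  6      k
#   bytes 7..8   number of genomes (uint16)
#   per genome   1-byte name length + name bytes (first-seen ID order)
#   then         the record section: for each prefix section in ascending
#                order, fixed-width records sorted strictly ascending by
#                packed key.
#
# A record is key_width + 4 bytes: the packed key (genome ID in the 8 least
# significant bits, k-mer remainder above it; key_width =
# ceil((bits_per_symbol * stored_symbols + 8)/8) bytes) followed by a uint32
# count. DNA databases with k > 10 store 1024 prefix sections holding the
# 2(k-5)-bit remainder (infix + suffix); k <= 10 and protein databases store
# one section holding the full code, with identical record framing, so every
# downstream tool is format-agnostic.
#
# <path>.mkc.idx        sidecar metadata
#   bytes 0..3   magic "MKCI"
#   byte  4      version (1)
#   byte  5      alphabet tag
#   byte  6      k
#   bytes 7..8   number of prefix sections (uint16: 1024 or 1)
#   per section  uint64 absolute byte offset into .mkc + uint64 record count
#
# Offsets are non-decreasing; empty sections carry the offset at which their
# records would start and a zero count, enabling random access by seeking
# directly to a prefix's byte range.

DB_MAGIC <- charToRaw("MKC1")
IDX_MAGIC <- charToRaw("MKCI")
DB_VERSION <- 1L
N_PREFIX_SECTIONS <- 1024L

alphabet_tag <- function(alphabet) if (alphabet == "dna") 0L else 1L
tag_alphabet <- function(tag) if (tag == 0L) "dna" else "protein"

# Does this (alphabet, k) use the 1024-way prefix split?
db_is_split <- function(alphabet, k) alphabet == "dna" && k > 10L

num_to_le <- function(x, nbytes) {
  out <- integer(nbytes * length(x))
  for (i in seq_along(x)) {
    v <- x[i]
    for (b in seq_len(nbytes)) {
      out[(i - 1L) * nbytes + b] <- v %% 256
      v <- v %/% 256
    }
  }
  as.raw(out)
}

le_to_num <- function(r, nbytes) {
  m <- matrix(as.integer(r), nrow = nbytes)
  as.numeric(256^(seq_len(nbytes) - 1) %*% m)
}

#' Write a binary k-mer database
#'
#' Serializes sorted, aggregated per-prefix records to `<path>.mkc` plus a
#' `<path>.mkc.idx` sidecar holding per-prefix byte offsets and record counts
#' for random access. See the package source for the bit-exact layout.
#'
#' @param records A `data.table` with columns `prefix` (integer section
#'   number; all 0 for single-section databases), `rem` (remainder string:
#'   the k-mer minus its 5-base prefix for split databases, the full k-mer
#'   otherwise), `gid`, `count`. Need not be pre-sorted; records are sorted
#'   and must be free of duplicate (prefix, rem, gid) keys.
#' @param genomes A `genome_table`.
#' @param k K-mer length.
#' @param alphabet `"dna"` or `"protein"`.
#' @param path Output path; `.mkc`/`.mkc.idx` are appended.
#' @return The `kmer_db` handle (invisibly), as from [read_kmer_db()].
#' @export
write_database <- function(records, genomes, k, alphabet, path) {
  k <- check_k(k, alphabet)
  split <- db_is_split(alphabet, k)
  n_sections <- if (split) N_PREFIX_SECTIONS else 1L
  n_sym <- if (split) k - PREFIX_BASES else k
  kw <- key_width_bytes(n_sym, alphabet)
  rw <- kw + 4L

  records <- data.table::as.data.table(records)
  if (nrow(records)) {
    records[, .sk := codec_sortkey(rem, alphabet)]
    data.table::setorderv(records, c("prefix", ".sk", "gid"))
    if (anyDuplicated(records, by = c("prefix", ".sk", "gid"))) {
      abort("duplicate (prefix, remainder, genome) records; aggregate first",
            "mafkmer_contract_error")
    }
    records[, .sk := NULL]
  }

  data_path <- paste0(path, ".mkc")
  idx_path <- paste0(path, ".mkc.idx")
  names <- genomes$names
  header <- c(DB_MAGIC, as.raw(DB_VERSION), as.raw(alphabet_tag(alphabet)),
              as.raw(k), num_to_le(length(names), 2L),
              unlist(lapply(names, function(nm) {
                b <- charToRaw(nm)
                if (length(b) > 255L) capacity_error("genome name longer than 255 bytes")
                c(as.raw(length(b)), b)
              })) %||% raw(0))

  con <- file(data_path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(header, con)
  offset <- length(header)
  offsets <- numeric(n_sections)
  counts <- numeric(n_sections)
  per_prefix <- if (nrow(records)) split(records, by = "prefix", keep.by = TRUE)
                else list()
  prefix_of <- as.integer(names(per_prefix))
  for (p in seq_len(n_sections) - 1L) {
    offsets[p + 1L] <- offset
    i <- match(p, prefix_of)
    if (!is.na(i)) {
      seg <- per_prefix[[i]]
      writeBin(pack_records_raw(seg$rem, seg$gid, seg$count, alphabet), con)
      counts[p + 1L] <- nrow(seg)
      offset <- offset + nrow(seg) * rw
    }
  }
  close(con)
  on.exit(NULL)

  icon <- file(idx_path, "wb")
  writeBin(c(IDX_MAGIC, as.raw(DB_VERSION), as.raw(alphabet_tag(alphabet)),
             as.raw(k), num_to_le(n_sections, 2L)), icon)
  for (p in seq_len(n_sections)) {
    writeBin(c(num_to_le(offsets[p], 8L), num_to_le(counts[p], 8L)), icon)
  }
  close(icon)
  invisible(read_kmer_db(path))
}

#' Open a binary k-mer database
#'
#' Reads the header and the byte-offset index; record sections are fetched
#' lazily by [lookup_kmer()] and [db_records()].
#'
#' @param path Database path with or without the `.mkc` suffix.
#' @return A `kmer_db` handle.
#' @export
read_kmer_db <- function(path) {
  path <- sub("\\.mkc$", "", path)
  data_path <- paste0(path, ".mkc")
  idx_path <- paste0(path, ".mkc.idx")
  if (!file.exists(data_path) || !file.exists(idx_path)) {
    format_error(sprintf("database files '%s(.idx)' not found", data_path))
  }
  con <- file(data_path, "rb")
  on.exit(close(con), add = TRUE)
  if (!identical(readBin(con, "raw", 4L), DB_MAGIC)) {
    format_error("bad magic in .mkc data file")
  }
  ver <- as.integer(readBin(con, "raw", 1L))
  if (ver != DB_VERSION) format_error(sprintf("unsupported format version %d", ver))
  alphabet <- tag_alphabet(as.integer(readBin(con, "raw", 1L)))
  k <- as.integer(readBin(con, "raw", 1L))
  n_gen <- le_to_num(readBin(con, "raw", 2L), 2L)
  names <- character(n_gen)
  for (i in seq_len(n_gen)) {
    len <- as.integer(readBin(con, "raw", 1L))
    names[i] <- rawToChar(readBin(con, "raw", len))
  }

  icon <- file(idx_path, "rb")
  on.exit(close(icon), add = TRUE)
  if (!identical(readBin(icon, "raw", 4L), IDX_MAGIC)) {
    format_error("bad magic in .mkc.idx metadata file")
  }
  iver <- as.integer(readBin(icon, "raw", 1L))
  if (iver != DB_VERSION) format_error("index version mismatch")
  ialph <- tag_alphabet(as.integer(readBin(icon, "raw", 1L)))
  ik <- as.integer(readBin(icon, "raw", 1L))
  if (ialph != alphabet || ik != k) {
    format_error("index header disagrees with data header")
  }
  n_sections <- as.integer(le_to_num(readBin(icon, "raw", 2L), 2L))
  idx <- readBin(icon, "raw", n_sections * 16L)
  m <- matrix(idx, nrow = 16L)
  offsets <- le_to_num(as.raw(m[1:8, ]), 8L)
  counts <- le_to_num(as.raw(m[9:16, ]), 8L)

  split <- db_is_split(alphabet, k)
  n_sym <- if (split) k - PREFIX_BASES else k
  structure(list(path = path, data_path = data_path, idx_path = idx_path,
                 alphabet = alphabet, k = k,
                 genomes = genome_table(names),
                 split = split, n_sym = n_sym,
                 key_width = key_width_bytes(n_sym, alphabet),
                 rec_width = key_width_bytes(n_sym, alphabet) + 4L,
                 index = data.table::data.table(
                   prefix = seq_len(n_sections) - 1L,
                   offset = offsets, count = counts)),
            class = "kmer_db")
}

#' @export
print.kmer_db <- function(x, ...) {
  cat(sprintf("<kmer_db %s k=%d: %s records in %d section(s), %d genomes>\n  %s\n",
              x$alphabet, x$k, format(sum(x$index$count), big.mark = ","),
              nrow(x$index), length(x$genomes$names), x$data_path))
  invisible(x)
}

# Read raw record bytes of one section.
read_section_raw <- function(db, prefix_want) {
  i <- which(db$index$prefix == prefix_want)
  if (length(i) != 1L) format_error(sprintf("no section %d in index", prefix_want))
  n <- db$index$count[i]
  if (n == 0L) return(raw(0))
  con <- file(db$data_path, "rb")
  on.exit(close(con))
  seek(con, db$index$offset[i])
  readBin(con, "raw", n * db$rec_width)
}

#' Materialize database records
#'
#' @param db A `kmer_db`.
#' @param prefixes Optional integer vector of prefix sections to read;
#'   default all.
#' @return `data.table(kmer, gid, genome, count)` in stored (code) order.
#' @export
db_records <- function(db, prefixes = NULL) {
  want <- db$index[db$index$count > 0L, ]
  if (!is.null(prefixes)) want <- want[want$prefix %in% prefixes, ]
  out <- vector("list", nrow(want))
  if (nrow(want)) {
    con <- file(db$data_path, "rb")
    on.exit(close(con))
    for (i in seq_len(nrow(want))) {
      seek(con, want$offset[i])
      r <- readBin(con, "raw", want$count[i] * db$rec_width)
      u <- unpack_records_raw(r, db$n_sym, db$alphabet)
      kmers <- if (db$split) {
        paste0(prefix_int_to_string(want$prefix[i]), u$rems)
      } else u$rems
      out[[i]] <- data.table::data.table(kmer = kmers, gid = u$gids,
                                         count = u$counts)
    }
  }
  dt <- data.table::rbindlist(out)
  if (nrow(dt) == 0L) {
    dt <- data.table::data.table(kmer = character(0), gid = integer(0),
                                 count = numeric(0))
  }
  dt[, genome := db$genomes$names[gid + 1L]]
  data.table::setcolorder(dt, c("kmer", "gid", "genome", "count"))
  dt[]
}

#' Convert a database to a count table
#'
#' @param db A `kmer_db`.
#' @return A `count_table` with the same entries.
#' @export
as_count_table <- function(db) {
  recs <- db_records(db)
  count_table(db$k, db$genomes, db$alphabet,
              counts = recs[, list(kmer, gid, count)])
}

#' Write a count table as a binary database
#'
#' @param ct A `count_table`.
#' @param path Output path (without suffix).
#' @return The `kmer_db` handle, invisibly.
#' @export
write_count_table_db <- function(ct, path) {
  dt <- data.table::copy(ct$counts)
  if (db_is_split(ct$alphabet, ct$k)) {
    recs <- data.table::data.table(
      prefix = if (nrow(dt)) kmer_prefix_int(dt$kmer) else integer(0),
      rem = substr(dt$kmer, PREFIX_BASES + 1L, ct$k),
      gid = dt$gid, count = dt$count)
  } else {
    recs <- data.table::data.table(prefix = rep(0L, nrow(dt)), rem = dt$kmer,
                                   gid = dt$gid, count = dt$count)
  }
  write_database(recs, ct$genomes, ct$k, ct$alphabet, path)
}

## ---- random access ---------------------------------------------------------

# Compare record i's remainder bytes (key bytes 2..kw, most significant last
# in LE storage) against a target remainder byte vector; -1/0/1.
cmp_rem <- function(bytes, i, rw, kw, target_be) {
  base <- (i - 1L) * rw
  for (j in seq_len(kw - 1L)) {          # most significant byte first
    b <- bytes[base + kw - j + 1L]
    t <- target_be[j]
    if (b < t) return(-1L)
    if (b > t) return(1L)
  }
  0L
}

#' Random-access lookup of one k-mer
#'
#' Seeks to the k-mer's prefix section via the byte-offset index (touching
#' only that section's byte range) and binary-searches the packed keys with
#' the genome-ID byte masked out.
#'
#' @param db A `kmer_db`.
#' @param kmer Query string of length `db$k`.
#' @return `data.table(genome, count)`, empty when the k-mer is absent.
#' @export
lookup_kmer <- function(db, kmer) {
  if (nchar(kmer) != db$k) {
    usage_error(sprintf("query length %d != database k %d", nchar(kmer), db$k))
  }
  kmer <- toupper(kmer)
  if (db$alphabet == "dna") kmer <- chartr("U", "T", kmer)
  if (is.null(kmer_digits(kmer, db$alphabet))) {
    usage_error(sprintf("query '%s' contains symbols outside the %s alphabet",
                        kmer, db$alphabet))
  }
  empty <- data.table::data.table(genome = character(0), count = numeric(0))
  prefix <- if (db$split) kmer_prefix_int(kmer) else 0L
  rem <- if (db$split) substr(kmer, PREFIX_BASES + 1L, db$k) else kmer
  r <- read_section_raw(db, prefix)
  n <- length(r) %/% db$rec_width
  if (n == 0L) return(empty)
  bytes <- as.integer(r)
  kw <- db$key_width
  rw <- db$rec_width
  # target remainder bytes, most significant first (gid byte excluded)
  tgt_raw <- pack_records_raw(rem, 0L, 0, db$alphabet)
  target_be <- as.integer(tgt_raw[kw:2])
  # lower bound by binary search on the genome-id-masked key
  lo <- 1L; hi <- n + 1L
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (cmp_rem(bytes, mid, rw, kw, target_be) < 0L) lo <- mid + 1L
    else hi <- mid
  }
  hits <- integer(0)
  i <- lo
  while (i <= n && cmp_rem(bytes, i, rw, kw, target_be) == 0L) {
    hits <- c(hits, i)
    i <- i + 1L
  }
  if (length(hits) == 0L) return(empty)
  sel <- as.raw(unlist(lapply(hits, function(i) {
    bytes[((i - 1L) * rw + 1L):(i * rw)]
  })))
  u <- unpack_records_raw(sel, db$n_sym, db$alphabet)
  data.table::data.table(genome = db$genomes$names[u$gids + 1L],
                         count = u$counts)
}

## ---- text outputs ----------------------------------------------------------

#' Write the combined ("map-reduced") dump
#'
#' One line per k-mer in ascending code order: the k-mer, then for each
#' genome holding it (ascending genome ID) a space-separated `NAME:COUNT`
#' pair — e.g. `ACGT hg38:3 mm10:1`.
#'
#' @param db A `kmer_db`.
#' @param path Output text file.
#' @return `path`, invisibly.
#' @export
dump_combined <- function(db, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  for (p in db$index$prefix[db$index$count > 0L]) {
    recs <- db_records(db, p)
    # records are stored sorted by (code, gid): group consecutively
    lines <- recs[, list(line = paste(kmer[1L],
                                      paste0(genome, ":",
                                             format(count, scientific = FALSE,
                                                    trim = TRUE),
                                             collapse = " "))),
                  by = list(kmer)]$line
    writeLines(lines, con)
  }
  invisible(path)
}

#' Write one dump file per genome
#'
#' Creates `NAME.kmers` in `dir` for every genome in the database's genome
#' table (an empty file when a genome holds no k-mers), each line
#' `KMER COUNT` in ascending code order. The union of the files carries the
#' same total count mass as the combined dump.
#'
#' @param db A `kmer_db`.
#' @param dir Output directory (created if needed).
#' @return Character vector of file paths, invisibly.
#' @export
dump_per_genome <- function(db, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  recs <- db_records(db)
  paths <- character(length(db$genomes$names))
  for (i in seq_along(db$genomes$names)) {
    nm <- db$genomes$names[i]
    paths[i] <- file.path(dir, paste0(nm, ".kmers"))
    sub <- recs[recs$gid == i - 1L, ]
    writeLines(if (nrow(sub)) paste(sub$kmer,
                                    format(sub$count, scientific = FALSE,
                                           trim = TRUE))
               else character(0),
               paths[i])
  }
  invisible(paths)
}
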