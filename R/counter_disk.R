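# Disk-based counting engine (default for DNA k > 10), after the external
# k-mer sorting design of the early KMC line: encoded k-mers are routed to
# 1024 bins by their 10-bit Prefix; full bins are partially sorted on the
# Infix (then suffix, then genome ID) and compacted; package managers merge
# sorted runs per Prefix and spill packages to temporary files once they
# exceed an element threshold; finally each Prefix's spilled segments are
# loaded, fully radix-sorted on the packed key, aggregated, and written to
# the binary database at precomputed byte offsets.
#
# Reader/manager/sorter "threads" are deterministic work partitions processed
# sequentially; the output contract is that the final database is
# byte-identical for every worker count and threshold choice.

DEFAULT_BIN_THRESHOLD <- 65536L
DEFAULT_PACKAGE_THRESHOLD <- 262144L

#' Route one k-mer occurrence to its Prefix bin
#'
#' @param kmer K-mer string (`k > 10`, DNA) or a `kmer_code`.
#' @param genome_id Integer genome ID.
#' @return A list with `prefix` (bin number, 0--1023) and `record`
#'   (`data.table(rem, gid, count = 1)` holding the infix+suffix remainder).
#' @export
assign_to_bin <- function(kmer, genome_id) {
  if (inherits(kmer, "kmer_code")) kmer <- decode_kmer(kmer)
  if (nchar(kmer) <= 10L) usage_error("binning requires k > 10")
  list(prefix = kmer_prefix_int(kmer),
       record = data.table::data.table(
         rem = substr(kmer, PREFIX_BASES + 1L, nchar(kmer)),
         gid = as.integer(genome_id), count = 1))
}

#' Partially sort and compact a bin's records
#'
#' Sorts by (infix, suffix, genome ID) — equivalently by remainder code then
#' genome ID — and merges adjacent records with identical keys by summing
#' counts.
#'
#' @param run `data.table(rem, gid, count)`.
#' @param alphabet Alphabet tag (affects the code ordering).
#' @return The sorted, compacted run.
#' @export
sort_and_compact <- function(run, alphabet = "dna") {
  if (nrow(run) == 0L) return(run)
  sk <- codec_sortkey(run$rem, alphabet)
  o <- order(sk, run$gid, method = "radix")
  sk <- sk[o]
  gid <- run$gid[o]
  # group breaks on the sorted (key, gid) stream mark distinct records
  first <- c(TRUE, sk[-1L] != sk[-length(sk)] | gid[-1L] != gid[-length(gid)])
  data.table::data.table(
    rem = run$rem[o][first], gid = gid[first],
    count = as.numeric(rowsum(run$count[o], cumsum(first), reorder = FALSE)))
}

# Merge sorted runs into one sorted run. data.table's radix sort over the
# concatenation is a linear-time stable merge for pre-sorted inputs; the
# merged stream stays sorted by (infix, suffix, genome ID). No compaction
# here — packages keep per-run duplicates until the final sort.
merge_sorted_runs <- function(runs, alphabet = "dna") {
  out <- data.table::rbindlist(runs)
  if (nrow(out)) {
    o <- order(codec_sortkey(out$rem, alphabet), out$gid, method = "radix")
    out <- data.table::data.table(rem = out$rem[o], gid = out$gid[o],
                                  count = out$count[o])
  }
  out[]
}

## ---- spill files -----------------------------------------------------------
## One spill file per package manager. Segments are serialized sorted runs
## written back-to-back; the manager records each segment's prefix, byte
## offset, length and record count.

SPILL_MAGIC <- charToRaw("MKSP")

spill_open <- function(temp_dir, id) {
  path <- file.path(temp_dir, sprintf("mafkmer_spill_%d_%s.bin", id,
                                      basename(tempfile(""))))
  con <- file(path, "wb")
  writeBin(c(SPILL_MAGIC, as.raw(DB_VERSION)), con)
  list(path = path, con = con, offset = 5, segments = list())
}

spill_write <- function(sp, prefix, run) {
  payload <- serialize(run, NULL, xdr = FALSE)
  writeBin(payload, sp$con)
  sp$segments[[length(sp$segments) + 1L]] <-
    list(prefix = prefix, offset = sp$offset, size = length(payload),
         nrec = nrow(run))
  sp$offset <- sp$offset + length(payload)
  sp
}

spill_read_segment <- function(path, seg) {
  con <- file(path, "rb")
  on.exit(close(con))
  seek(con, seg$offset)
  unserialize(readBin(con, "raw", seg$size))
}

# 30% readers / 70% package managers: the default apportionment of a single
# total worker count. Configuration only — never affects the result.
apportion_threads <- function(threads) {
  threads <- max(1L, as.integer(threads))
  readers <- max(1L, as.integer(round(0.3 * threads)))
  managers <- max(1L, threads - readers)
  list(readers = readers, managers = managers)
}

#' Count a MAF file with the disk-based engine
#'
#' End-to-end result is independent of the reader/manager counts and both
#' thresholds: the same input always yields a byte-identical database.
#'
#' @param path MAF file (plain or gzipped).
#' @param k K-mer length, `10 < k <= 64` (DNA only; protein counting uses the
#'   hashmap engine).
#' @param out Output database path (without suffix); defaults to a tempfile.
#' @param spec A `filter_spec`.
#' @param readers,managers Reader / package-manager partition counts. When
#'   only `threads` is given, it is apportioned 30% readers / 70% managers.
#' @param threads Total worker count (alternative to `readers` + `managers`).
#' @param bin_threshold Records at which a Prefix bin is partially sorted,
#'   compacted and handed to its package manager.
#' @param package_threshold Records at which a package is spilled to disk.
#' @param temp_dir Directory for spill files (deleted on success).
#' @param genomes Optional pre-built `genome_table`.
#' @return A `kmer_db` handle on the written database.
#' @export
count_file_disk <- function(path, k, out = tempfile("mafkmer_db_"),
                            spec = filter_spec(),
                            readers = NULL, managers = NULL, threads = NULL,
                            bin_threshold = DEFAULT_BIN_THRESHOLD,
                            package_threshold = DEFAULT_PACKAGE_THRESHOLD,
                            temp_dir = tempdir(), genomes = NULL) {
  k <- check_k(k, "dna")
  if (k <= 10L) {
    usage_error("disk engine requires k > 10; use count_file_small for small k")
  }
  if (is.null(readers) || is.null(managers)) {
    ap <- apportion_threads(threads %||% 1L)
    readers <- readers %||% ap$readers
    managers <- managers %||% ap$managers
  }
  readers <- max(1L, as.integer(readers))
  managers <- max(1L, as.integer(managers))
  bin_threshold <- max(1L, as.integer(bin_threshold))
  package_threshold <- max(1L, as.integer(package_threshold))

  blocks <- read_maf(path)
  gt <- genomes %||% build_genome_table(blocks)
  warn_missing_genomes(spec, gt)

  bins <- new.env(parent = emptyenv())        # prefix -> list(chunks, n)
  packages <- new.env(parent = emptyenv())    # prefix -> list(runs, n)
  spills <- lapply(seq_len(managers), function(i) spill_open(temp_dir, i))
  cleanup <- function() {
    for (sp in spills) {
      try(close(sp$con), silent = TRUE)
      try(unlink(sp$path), silent = TRUE)
    }
  }
  on.exit(cleanup(), add = TRUE)

  manager_of <- function(prefix) prefix %% managers + 1L

  flush_package <- function(key) {
    pk <- packages[[key]]
    if (is.null(pk) || pk$n == 0L) return(invisible())
    prefix <- as.integer(key)
    run <- merge_sorted_runs(pk$runs)
    m <- manager_of(prefix)
    spills[[m]] <<- spill_write(spills[[m]], prefix, run)
    packages[[key]] <- list(runs = list(), n = 0L)
    invisible()
  }

  push_to_package <- function(prefix, run) {
    key <- as.character(prefix)
    pk <- packages[[key]] %||% list(runs = list(), n = 0L)
    pk$runs[[length(pk$runs) + 1L]] <- run
    pk$n <- pk$n + nrow(run)
    packages[[key]] <- pk
    if (pk$n >= package_threshold) flush_package(key)
  }

  flush_bin <- function(key) {
    bn <- bins[[key]]
    if (is.null(bn) || bn$n == 0L) return(invisible())
    run <- sort_and_compact(data.table::rbindlist(bn$chunks))
    bins[[key]] <- list(chunks = list(), n = 0L)
    push_to_package(as.integer(key), run)
    invisible()
  }

  # reader phase: round-robin over contiguous chunks
  chunks <- partition_blocks(blocks, readers)
  for (ch in chunks) {
    for (b in ch) {
      w <- block_windows(b, k, spec, "dna")
      if (is.null(w) || nrow(w) == 0L) next
      gids <- genome_id(gt, w$genome)
      prefixes <- kmer_prefix_int(w$kmer)
      rems <- substr(w$kmer, PREFIX_BASES + 1L, k)
      for (rows in split(seq_len(nrow(w)), prefixes)) {
        key <- as.character(prefixes[rows[1L]])
        piece <- data.table::data.table(rem = rems[rows], gid = gids[rows],
                                        count = 1)
        bn <- bins[[key]] %||% list(chunks = list(), n = 0L)
        bn$chunks[[length(bn$chunks) + 1L]] <- piece
        bn$n <- bn$n + length(rows)
        bins[[key]] <- bn
        if (bn$n >= bin_threshold) flush_bin(key)
      }
    }
  }
  # end-of-input flush
  for (key in ls(bins)) flush_bin(key)
  for (key in ls(packages)) flush_package(key)
  for (i in seq_along(spills)) {
    close(spills[[i]]$con)
    spills[[i]]$con <- NULL
  }

  # sorter phase: full radix sort + aggregation per prefix, round-robin
  # across N + M sorter partitions (sequential; order is immaterial to the
  # result because output offsets are precomputed per prefix)
  segs_by_prefix <- list()
  for (sp in spills) {
    for (seg in sp$segments) {
      key <- as.character(seg$prefix)
      segs_by_prefix[[key]] <- c(segs_by_prefix[[key]],
                                 list(list(path = sp$path, seg = seg)))
    }
  }
  present <- sort(as.integer(names(segs_by_prefix)))
  final <- vector("list", length(present))
  for (i in seq_along(present)) {
    key <- as.character(present[i])
    runs <- lapply(segs_by_prefix[[key]],
                   function(s) spill_read_segment(s$path, s$seg))
    agg <- finalize_prefix(runs)
    agg[, prefix := present[i]]
    final[[i]] <- agg
  }
  records <- data.table::rbindlist(final)
  if (nrow(records) == 0L) {
    records <- data.table::data.table(prefix = integer(0), rem = character(0),
                                      gid = integer(0), count = numeric(0))
  }
  db <- write_database(records, gt, k, "dna", out)
  cleanup()
  on.exit(NULL)
  db
}

#' Fully sort and aggregate one Prefix's spilled segments
#'
#' Loads all sorted runs of one Prefix, radix-sorts the union by the packed
#' key (remainder then genome ID) and sums counts of duplicate keys.
#'
#' @param runs List of `data.table(rem, gid, count)` runs.
#' @param alphabet Alphabet tag.
#' @return One aggregated sorted `data.table(rem, gid, count)`.
#' @export
finalize_prefix <- function(runs, alphabet = "dna") {
  all <- data.table::rbindlist(runs)
  if (nrow(all) == 0L) return(all)
  sort_and_compact(all, alphabet)
}
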