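# Hashmap counting engine (default for k <= 10): per-chunk associative
# accumulation followed by a deterministic sequential merge. Works for any
# encodable k via `allow_any_k`, which makes the two engines cross-checkable.

#' Construct an empty count table
#'
#' A `count_table` holds per-(k-mer, genome) counts: the alphabet tag, k, the
#' genome table, and a `data.table` with columns `kmer`, `gid`, `count`
#' sorted in code order then genome ID. Zero counts are never stored.
#'
#' @param k K-mer length.
#' @param genomes A `genome_table`.
#' @param alphabet `"dna"` or `"protein"`.
#' @param counts Optional `data.table(kmer, gid, count)`.
#' @return A `count_table`.
#' @export
count_table <- function(k, genomes, alphabet = "dna", counts = NULL) {
  k <- check_k(k, alphabet)
  if (is.null(counts)) {
    counts <- data.table::data.table(kmer = character(0), gid = integer(0),
                                     count = numeric(0))
  }
  ct <- structure(list(alphabet = alphabet, k = k, genomes = genomes,
                       counts = counts),
                  class = "count_table")
  sort_count_table(ct)
}

sort_count_table <- function(ct) {
  dt <- ct$counts
  if (nrow(dt)) {
    dt[, `:=`(.sk = codec_sortkey(kmer, ct$alphabet))]
    data.table::setorderv(dt, c(".sk", "gid"))
    dt[, .sk := NULL]
  }
  ct$counts <- dt
  ct
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table %s k=%d: %d (k-mer, genome) entries, %d distinct k-mers, %d genomes>\n",
              x$alphabet, x$k, nrow(x$counts),
              data.table::uniqueN(x$counts$kmer), length(x$genomes$names)))
  if (nrow(x$counts)) {
    print(utils::head(x$counts, 6L))
    if (nrow(x$counts) > 6L) cat("  ...\n")
  }
  invisible(x)
}

#' Total count mass of a count table
#'
#' @param ct A `count_table`.
#' @return Sum of all stored counts (the number of accepted windows).
#' @export
total_counts <- function(ct) sum(ct$counts$count)

#' Count one block into a table
#'
#' Slides a width-k window over every ungapped, uppercased `s` line that
#' passes the filters; windows that encode successfully and pass the
#' per-base quality rule each add 1 to `(k-mer, genome)`. All `s` lines,
#' including the block's reference, contribute.
#'
#' @param block A `maf_block`.
#' @param ct A `count_table` (its genome table must cover the block).
#' @param spec A `filter_spec`.
#' @return The updated `count_table`.
#' @export
count_block <- function(block, ct, spec = filter_spec()) {
  w <- block_windows(block, ct$k, spec, ct$alphabet)
  if (is.null(w)) return(ct)
  w[, gid := genome_id(ct$genomes, genome)]
  inc <- w[, list(count = as.numeric(.N)), by = list(kmer, gid)]
  merged <- data.table::rbindlist(list(ct$counts, inc))
  ct$counts <- merged[, list(count = sum(count)), by = list(kmer, gid)]
  sort_count_table(ct)
}

#' Merge count tables pointwise
#'
#' Counts add; the merge is associative and commutative. All tables must
#' share k, alphabet and genome table.
#'
#' @param tables A list of `count_table` objects.
#' @return The merged `count_table`.
#' @export
merge_count_tables <- function(tables) {
  if (length(tables) == 0L) usage_error("no tables to merge")
  t1 <- tables[[1L]]
  for (t in tables[-1L]) {
    if (t$k != t1$k || t$alphabet != t1$alphabet ||
        !identical(t$genomes$names, t1$genomes$names)) {
      abort("cannot merge count tables with different k/alphabet/genomes",
            "mafkmer_contract_error")
    }
  }
  all <- data.table::rbindlist(lapply(tables, `[[`, "counts"))
  t1$counts <- if (nrow(all)) all[, list(count = sum(count)),
                                  by = list(kmer, gid)]
               else all
  sort_count_table(t1)
}

#' Count a MAF file with the hashmap engine
#'
#' The file is partitioned at block boundaries into `partitions` chunks, each
#' counted into its own local table, and the chunk tables are merged
#' sequentially. The result is identical for every partition count, so chunked
#' (potentially concurrent) execution and single-pass execution agree.
#'
#' @param path MAF file (plain or gzipped).
#' @param k K-mer length; the hashmap engine is the default choice for
#'   `k <= 10`.
#' @param spec A `filter_spec`.
#' @param partitions Number of chunks (>= 1).
#' @param alphabet `"dna"` or `"protein"`.
#' @param allow_any_k Permit `k > 10` (used to cross-check the disk engine).
#' @param genomes Optional pre-built `genome_table`; by default it is built
#'   from the file (first-seen order), independent of the chunking.
#' @return A `count_table`.
#' @export
count_file_small <- function(path, k, spec = filter_spec(), partitions = 1L,
                             alphabet = "dna", allow_any_k = FALSE,
                             genomes = NULL) {
  k <- check_k(k, alphabet)
  if (alphabet == "dna" && k > 10L && !allow_any_k) {
    usage_error("hashmap engine is for k <= 10; use the disk engine or allow_any_k = TRUE")
  }
  blocks <- read_maf(path)
  gt <- genomes %||% build_genome_table(blocks)
  warn_missing_genomes(spec, gt)
  chunks <- partition_blocks(blocks, partitions)
  locals <- lapply(chunks, function(ch) {
    ct <- count_table(k, gt, alphabet)
    for (b in ch) ct <- count_block(b, ct, spec)
    ct
  })
  if (length(locals) == 0L) return(count_table(k, gt, alphabet))
  merge_count_tables(c(list(count_table(k, gt, alphabet)), locals))
}
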