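# User-facing front door: pick a counting engine, count, and hand back a
# count table and/or a binary database.

#' Count k-mer occurrences per genome in a MAF file
#'
#' Selects the hashmap engine for `k <= 10` (and all protein input) and the
#' disk-based engine for DNA `k > 10`; both produce identical results where
#' their ranges overlap.
#'
#' @param path MAF file, plain or gzip-compressed.
#' @param k K-mer length (DNA/RNA: 1--64; protein: 1--25).
#' @param alphabet `"dna"` or `"protein"`.
#' @param engine `"auto"` (default), `"map"`, or `"disk"`.
#' @param spec A [filter_spec()].
#' @param db_path If non-`NULL`, also write the binary database here and
#'   return its handle in the result.
#' @param ... Passed to the selected engine ([count_file_small()] or
#'   [count_file_disk()]): `partitions`, `readers`, `managers`, `threads`,
#'   `bin_threshold`, `package_threshold`, `temp_dir`, ...
#' @return A `count_table`; when `db_path` is given, the `kmer_db` handle is
#'   attached as attribute `"db"`.
#' @examples
#' maf <- tempfile(fileext = ".maf")
#' writeLines(c("a score=12.5",
#'              "s hg38.chr1 0 4 + 1000 AC-GT",
#'              "s mm10.chr2 5 4 - 2000 ACG-T"), maf)
#' count_maf(maf, k = 2)
#' @export
count_maf <- function(path, k, alphabet = c("dna", "protein"),
                      engine = c("auto", "map", "disk"),
                      spec = filter_spec(), db_path = NULL, ...) {
  alphabet <- match.arg(alphabet)
  engine <- match.arg(engine)
  k <- check_k(k, alphabet)
  if (engine == "auto") {
    engine <- if (alphabet == "dna" && k > 10L) "disk" else "map"
  }
  if (engine == "disk" && alphabet == "protein") {
    usage_error("protein counting uses the map engine (25-symbol alphabet)")
  }
  if (engine == "disk") {
    out <- db_path %||% tempfile("mafkmer_db_")
    db <- count_file_disk(path, k, out = out, spec = spec, ...)
    ct <- as_count_table(db)
    if (!is.null(db_path)) attr(ct, "db") <- db else {
      unlink(paste0(out, c(".mkc", ".mkc.idx")))
    }
    ct
  } else {
    ct <- count_file_small(path, k, spec = spec, alphabet = alphabet,
                           allow_any_k = TRUE, ...)
    if (!is.null(db_path)) attr(ct, "db") <- write_count_table_db(ct, db_path)
    ct
  }
}
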