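# Shared test helpers: tiny hand-written MAF texts, count-table comparison,
# and an independent G-quadruplex scanner used as a second implementation of
# the consensus.

toy_maf_lines <- function() {
  c("##maf version=1",
    "",
    "a score=23.0",
    "s hg38.chr1 0 4 + 1000 AC-GT",
    "s mm10.chr2 5 4 - 2000 ACG-T",
    "q mm10.chr2      99F-1",
    "",
    "a",
    "s hg38.chr1 4 6 + 1000 ACGTAC",
    "s panTro6.chr3 0 6 + 5000 ACGTNC",
    "")
}

write_toy_maf <- function(lines = toy_maf_lines()) {
  path <- tempfile(fileext = ".maf")
  writeLines(lines, path)
  path
}

gzip_file <- function(path) {
  gz <- paste0(path, ".gz")
  con <- gzfile(gz, "wb")
  writeBin(readBin(path, "raw", file.size(path)), con)
  close(con)
  gz
}

# value-level equality of count tables (ignoring data.table internals)
expect_same_counts <- function(a, b) {
  expect_identical(a$counts$kmer, b$counts$kmer)
  expect_identical(a$counts$gid, b$counts$gid)
  expect_identical(as.numeric(a$counts$count), as.numeric(b$counts$count))
  expect_identical(a$genomes$names, b$genomes$names)
}

ct_as_df <- function(ct) {
  data.frame(kmer = ct$counts$kmer,
             genome = ct$genomes$names[ct$counts$gid + 1L],
             count = as.numeric(ct$counts$count))
}

md5_of_db <- function(db) {
  unname(c(tools::md5sum(db$data_path), tools::md5sum(db$idx_path)))
}

# Independent G-quadruplex consensus scanner: recursive segment matcher for
# G{3+} (N{1-7} G{3+}) x3, where N is any base; substring semantics.
g4_scan <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  segs <- list(c("G", 3, n), c("N", 1, 7), c("G", 3, n), c("N", 1, 7),
               c("G", 3, n), c("N", 1, 7), c("G", 3, n))
  match_from <- function(pos, si) {
    if (si > length(segs)) return(TRUE)
    seg <- segs[[si]]
    lo <- as.integer(seg[2]); hi <- as.integer(seg[3])
    for (len in lo:hi) {
      if (pos + len - 1L > n) return(FALSE)
      piece <- chars[pos:(pos + len - 1L)]
      ok <- if (seg[1] == "G") all(piece == "G")
            else all(piece %in% c("A", "C", "G", "T"))
      if (!ok) {
        if (seg[1] == "G" && len == lo) return(FALSE) else break
      }
      if (match_from(pos + len, si + 1L)) return(TRUE)
    }
    FALSE
  }
  for (start in seq_len(n)) {
    if (match_from(start, 1L)) return(TRUE)
  }
  FALSE
}

random_kmers <- function(n, k, alphabet = c("A", "C", "G", "T")) {
  vapply(seq_len(n), function(i) {
    paste0(sample(alphabet, k, replace = TRUE), collapse = "")
  }, character(1))
}
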