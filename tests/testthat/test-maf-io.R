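test_that("a two-block toy MAF parses into blocks with scores, q lines and info lines", {
  path <- write_toy_maf()
  blocks <- read_maf(path)
  expect_length(blocks, 2L)
  expect_equal(blocks[[1]]$score, 23.0)
  expect_true(is.na(blocks[[2]]$score))
  expect_length(blocks[[1]]$sequences, 2L)
  expect_identical(blocks[[1]]$sequences[[1]]$src, "hg38.chr1")
  expect_identical(blocks[[1]]$sequences[[2]]$strand, "-")
  expect_null(blocks[[1]]$qualities[[1]])
  expect_identical(blocks[[1]]$qualities[[2]]$qualities, "99F-1")
})

test_that("i and e lines are retained but never contribute sequences", {
  lines <- c("a score=1.0",
             "s hg38.chr1 0 4 + 1000 ACGT",
             "i hg38.chr1 N 0 C 0",
             "e mm10.chr3 0 4 + 2000 I",
             "")
  blocks <- read_maf(write_toy_maf(lines))
  expect_length(blocks, 1L)
  expect_length(blocks[[1]]$sequences, 1L)
  expect_length(blocks[[1]]$info, 2L)
})

test_that("gzipped input yields an identical block stream", {
  path <- write_toy_maf()
  gz <- gzip_file(path)
  expect_identical(read_maf(gz), read_maf(path))
})

test_that("empty files and degenerate inputs are handled", {
  empty <- tempfile()
  writeLines(character(0), empty)
  expect_length(read_maf(empty), 0L)
  only_comments <- write_toy_maf(c("##maf version=1", "# nothing here", ""))
  expect_length(read_maf(only_comments), 0L)
  expect_error(read_maf(tempfile("no_such_")), class = "mafkmer_io_error")
})

test_that("malformed s lines and non-MAF content raise parse errors naming the line", {
  bad <- write_toy_maf(c("a", "s hg38.chr1 0 4 + ACGT", ""))
  err <- expect_error(read_maf(bad), class = "mafkmer_parse_error")
  expect_match(conditionMessage(err), "line 2")
  notmaf <- write_toy_maf(c(">seq1", "ACGTACGT"))
  expect_error(read_maf(notmaf), class = "mafkmer_parse_error")
})

test_that("size-field inconsistencies warn instead of failing", {
  sloppy <- write_toy_maf(c("a", "s hg38.chr1 0 7 + 1000 AC-GT", ""))
  expect_warning(blocks <- read_maf(sloppy), "non-gap")
  expect_length(blocks, 1L)
})

test_that("non-gap character count matches the size field on generated fixtures", {
  f <- tempfile(fileext = ".maf")
  generate_maf(fixture_config(seed = 11, n_genomes = 3, n_blocks = 5), f)
  expect_silent(blocks <- read_maf(f))
  for (b in blocks) {
    for (s in b$sequences) {
      expect_identical(nchar(gsub("-", "", s$text, fixed = TRUE)),
                       as.integer(s$size))
    }
  }
})

test_that("parse -> serialize -> parse round-trips block structure", {
  f <- tempfile(fileext = ".maf")
  generate_maf(fixture_config(seed = 5, n_genomes = 2, n_blocks = 4), f)
  blocks <- read_maf(f)
  reser <- unlist(lapply(blocks, function(b) {
    a <- if (is.na(b$score)) "a" else sprintf("a score=%s", format(b$score))
    body <- unlist(lapply(seq_along(b$sequences), function(i) {
      s <- b$sequences[[i]]
      ln <- sprintf("s %s %d %d %s %d %s", s$src, s$start, s$size, s$strand,
                    s$src_size, s$text)
      if (!is.null(b$qualities[[i]])) {
        ln <- c(ln, sprintf("q %s %s", b$qualities[[i]]$src,
                            b$qualities[[i]]$qualities))
      }
      ln
    }))
    c(a, body, "")
  }))
  f2 <- write_toy_maf(reser)
  expect_equal(read_maf(f2), blocks)
})

test_that("genome names come from the src prefix before the first dot", {
  expect_identical(extract_genome_id("hg38.chr1"), "hg38")
  expect_identical(extract_genome_id("scaffold_12"), "scaffold_12")
  expect_identical(extract_genome_id("panTro6.chrUn.scaf17"), "panTro6")
  expect_error(extract_genome_id(""), class = "mafkmer_parse_error")
})

test_that("genome table assigns IDs in first-seen order, deduplicated, capped at 256", {
  blocks <- read_maf(write_toy_maf())
  gt <- build_genome_table(blocks)
  expect_identical(gt$names, c("hg38", "mm10", "panTro6"))
  expect_identical(genome_id(gt, c("hg38", "panTro6")), c(0L, 2L))
  # 50 repeats of the same genome collapse to one entry
  many <- rep(c("a score=1", "s hg38.chr1 0 2 + 10 AC", ""), 50L)
  expect_identical(build_genome_table(read_maf(write_toy_maf(many)))$names,
                   "hg38")
  err <- expect_error(genome_table(sprintf("g%03d", 1:257)),
                      class = "mafkmer_capacity_error")
  expect_match(conditionMessage(err), "8-bit")
})

test_that("ungap removes gaps, uppercases and aligns quality values (F -> 10)", {
  expect_identical(ungap("AC-GT")$seq, "ACGT")
  expect_identical(ungap("ac-gt")$seq, "ACGT")
  u <- ungap("AC-GT", "99-F1")
  expect_identical(u$seq, "ACGT")
  expect_identical(u$qual, c(9L, 9L, 10L, 1L))
  expect_error(ungap("ACGT", "99"), class = "mafkmer_consistency_error")
})
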