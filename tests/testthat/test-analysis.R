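db_from_counts <- function(counts, genomes, k = 4L, alphabet = "dna") {
  gt <- genome_table(genomes)
  ct <- count_table(k, gt, alphabet,
                    counts = data.table::data.table(kmer = counts$kmer,
                                                    gid = counts$gid,
                                                    count = counts$count))
  write_count_table_db(ct, tempfile())
}

test_that("top_variance matches a full-sort reference, absent genomes counting 0", {
  f <- tempfile(fileext = ".maf")
  generate_maf(fixture_config(seed = 61, n_genomes = 4, n_blocks = 8), f)
  db <- count_file_disk(f, 11, out = tempfile())
  recs <- db_records(db)
  G <- length(db$genomes$names)
  ref <- recs[, list(std = stats::sd(c(count, rep(0, G - length(count))))),
              by = list(kmer)]
  ref[, sk := mafkmer:::codec_sortkey(kmer, "dna")]
  data.table::setorderv(ref, c("std", "sk"), order = c(-1L, 1L))
  for (top in c(1L, 5L, 17L, nrow(ref), nrow(ref) + 10L)) {
    got <- top_variance(db, top)
    n <- min(top, nrow(ref))
    expect_identical(got$kmer, ref$kmer[seq_len(n)])
    expect_equal(got$std, ref$std[seq_len(n)], tolerance = 1e-12)
  }
})

test_that("variance ties are broken by ascending k-mer code", {
  # three k-mers with identical count vectors -> identical std
  db <- db_from_counts(list(kmer = c("TTTT", "AAAA", "CCCC"),
                            gid = c(0L, 0L, 0L), count = c(2, 2, 2)),
                       c("g1", "g2"))
  got <- top_variance(db, 2)
  expect_identical(got$kmer, c("AAAA", "CCCC"))
})

test_that("single-genome databases have zero standard deviation everywhere", {
  db <- db_from_counts(list(kmer = c("ACGT", "GGGG"), gid = c(0L, 0L),
                            count = c(5, 1)), "only")
  got <- top_variance(db, 10)
  expect_identical(got$std, c(0, 0))
  expect_identical(got$kmer, c("ACGT", "GGGG"))
})

test_that("genome_stats reproduces the worked example to high precision", {
  # counts {1, 2, 3, 10}: mean 4, median 2.5, sample variance 50/3,
  # m2 = 12.5, m3 = 45, g1 = 45 / 12.5^1.5
  db <- db_from_counts(list(kmer = c("AAAA", "ACGT", "CCCC", "GGGG"),
                            gid = rep(0L, 4), count = c(1, 2, 3, 10)),
                       "g1")
  st <- genome_stats(db, "g1")
  expect_identical(st$n, 4L)
  expect_identical(st$min, 1)
  expect_identical(st$max, 10)
  expect_equal(st$mean, 4, tolerance = 1e-12)
  expect_equal(st$median, 2.5, tolerance = 1e-12)
  expect_equal(st$variance, 50 / 3, tolerance = 1e-12)
  expect_equal(st$skewness, 45 / 12.5^1.5, tolerance = 1e-12)
})

test_that("genome_stats is invariant to chunk size and matches direct formulas", {
  f <- tempfile(fileext = ".maf")
  generate_maf(fixture_config(seed = 62, n_genomes = 3, n_blocks = 6), f)
  db <- count_file_disk(f, 12, out = tempfile())
  recs <- db_records(db)
  for (g in db$genomes$names) {
    x <- recs$count[recs$genome == g]
    ref <- genome_stats(db, g)
    expect_equal(ref$mean, mean(x), tolerance = 1e-12)
    expect_equal(ref$median, stats::median(x), tolerance = 1e-12)
    expect_equal(ref$variance, stats::var(x), tolerance = 1e-12)
    m2 <- mean((x - mean(x))^2); m3 <- mean((x - mean(x))^3)
    expect_equal(ref$skewness, if (m2 > 0) m3 / m2^1.5 else 0,
                 tolerance = 1e-9)
    for (cs in c(1L, 3L, 1000L)) {
      alt <- genome_stats(db, g, chunk_size = cs)
      expect_equal(alt[c("mean", "variance", "skewness", "median")],
                   ref[c("mean", "variance", "skewness", "median")],
                   tolerance = 1e-12)
    }
  }
  expect_error(genome_stats(db, "nosuch"), class = "mafkmer_lookup_error")
})

test_that("constant counts give zero skewness; n = 1 gives zero variance", {
  db <- db_from_counts(list(kmer = c("AAAA", "CCCC"), gid = c(0L, 0L),
                            count = c(7, 7)), "g1")
  st <- genome_stats(db, "g1")
  expect_identical(st$skewness, 0)
  db1 <- db_from_counts(list(kmer = "AAAA", gid = 0L, count = 9), "g1")
  st1 <- genome_stats(db1, "g1")
  expect_identical(st1$variance, 0)
  expect_identical(st1$n, 1L)
})

test_that("expression parsing honors precedence, parentheses and reports positions", {
  e <- parse_expr("a>1 || b>1 && c>1")
  expect_identical(e$type, "or")            # && binds tighter than ||
  expect_identical(e$rhs$type, "and")
  e2 <- parse_expr("(a>1 || b>1) && c>1")
  expect_identical(e2$type, "and")
  err <- expect_error(parse_expr("a >> 1"), class = "mafkmer_parse_error")
  expect_match(conditionMessage(err), "position")
  expect_error(parse_expr("a > "), class = "mafkmer_parse_error")
  expect_error(parse_expr("(a>1"), class = "mafkmer_parse_error")
  expect_error(parse_expr("a>1 b>1"), class = "mafkmer_parse_error")
})

test_that("filter_database evaluates counts with absent genomes as zero", {
  db <- db_from_counts(list(kmer = c("AAAA", "AAAA", "CCCC", "GGGG"),
                            gid = c(0L, 1L, 0L, 1L),
                            count = c(3, 1, 2, 5)),
                       c("g1", "g2"))
  got <- function(expr) sort(unique(filter_database(db, expr)$kmer))
  expect_identical(got("g1>1 && g2>0"), "AAAA")
  expect_identical(got("g1=0"), "GGGG")               # absent -> 0
  expect_identical(got("g1>1 || g2>1"), c("AAAA", "CCCC", "GGGG"))
  expect_identical(got("g1>0 && (g2=1 || g2=0)"), c("AAAA", "CCCC"))
  expect_error(filter_database(db, "nosuch>1"), class = "mafkmer_lookup_error")
  # writing the filtered set as a database round-trips
  res <- filter_database(db, "g1>1", out = tempfile())
  db2 <- attr(res, "db")
  expect_identical(sort(unique(db_records(db2)$kmer)), c("AAAA", "CCCC"))
})

test_that("the G4 pattern agrees with an independent scanner on curated cases", {
  yes <- c("GGGAGGGAGGGAGGG",            # minimal quadruplex
           "TTGGGGTTAGGGTTAGGGTTAGGGTT", # human telomere repeat
           "GGGGGGGGGGGGGGGG")           # long G run satisfies all four
  no <- c("GGGAGGGAGGGAGG",              # fourth run too short
          "GGGAAAAAAAAGGGAGGGAGGG",      # 8-base loop too long
          "ACGTACGTACGTACGT")
  for (s in yes) {
    expect_true(grepl(g4_pattern(), s, perl = TRUE))
    expect_true(g4_scan(s))
  }
  for (s in no) {
    expect_false(grepl(g4_pattern(), s, perl = TRUE))
    expect_false(g4_scan(s))
  }
})

test_that("query modes: list, comma string, file, regex, g4", {
  f <- tempfile(fileext = ".maf")
  generate_maf(fixture_config(seed = 63, n_genomes = 3, n_blocks = 6), f)
  db <- count_file_disk(f, 11, out = tempfile())
  recs <- db_records(db)
  kms <- unique(recs$kmer)[1:3]
  ql <- query_kmers(db, kmers = kms)
  expect_identical(ql, query_kmers(db, kmers = paste(kms, collapse = ",")))
  qf <- tempfile(); writeLines(kms, qf)
  expect_identical(ql, query_kmers(db, file = qf))
  expect_identical(sort(unique(ql$kmer)), sort(kms))
  # regex is substring search; anchors restore full-match behavior
  qr <- query_kmers(db, regex = "^ACG")
  expect_identical(sort(unique(qr$kmer)),
                   sort(unique(recs$kmer[startsWith(recs$kmer, "ACG")])))
  qg <- query_kmers(db, g4 = TRUE)
  expect_identical(sort(unique(qg$kmer)),
                   sort(unique(recs$kmer[vapply(recs$kmer, g4_scan,
                                                logical(1))])))
  expect_error(query_kmers(db, regex = "(("), class = "mafkmer_pattern_error")
  expect_error(query_kmers(db), class = "mafkmer_usage_error")
  expect_error(query_kmers(db, kmers = "ACGT", regex = "A"),
               class = "mafkmer_usage_error")
  expect_error(query_kmers(db, kmers = "ACGT"), class = "mafkmer_usage_error")
})
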