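make_db <- function(seed = 51, k = 12, n_genomes = 4, n_blocks = 8, ...) {
  f <- tempfile(fileext = ".maf")
  generate_maf(fixture_config(seed = seed, n_genomes = n_genomes,
                              n_blocks = n_blocks, ...), f)
  list(maf = f, db = count_file_disk(f, k, out = tempfile()))
}

test_that("the data file header carries magic, version, alphabet, k and genomes", {
  x <- make_db()
  con <- file(x$db$data_path, "rb")
  on.exit(close(con))
  expect_identical(readBin(con, "raw", 4L), charToRaw("MKC1"))
  expect_identical(as.integer(readBin(con, "raw", 1L)), 1L)  # version
  expect_identical(as.integer(readBin(con, "raw", 1L)), 0L)  # dna
  expect_identical(as.integer(readBin(con, "raw", 1L)), 12L) # k
  n_gen <- as.integer(readBin(con, "raw", 1L)) +
    256L * as.integer(readBin(con, "raw", 1L))
  expect_identical(n_gen, 4L)
  len <- as.integer(readBin(con, "raw", 1L))
  expect_identical(rawToChar(readBin(con, "raw", len)), "gen001")
})

test_that("the index has 1024 sections with non-decreasing offsets summing to the file size", {
  x <- make_db()
  db <- x$db
  expect_identical(nrow(db$index), 1024L)
  expect_true(all(diff(db$index$offset) >= 0))
  expect_identical(db$index$offset + db$index$count * db$rec_width,
                   c(db$index$offset[-1L],
                     as.numeric(file.size(db$data_path))))
  # empty sections carry the offset where their records would start
  expect_true(any(db$index$count == 0))
})

test_that("small-k and protein databases use a single section", {
  f <- tempfile(fileext = ".maf")
  generate_maf(fixture_config(seed = 52, n_genomes = 2, n_blocks = 4), f)
  ct <- count_file_small(f, 4)
  db <- write_count_table_db(ct, tempfile())
  expect_identical(nrow(db$index), 1L)
  expect_same_counts(as_count_table(db), ct)

  fp <- tempfile(fileext = ".maf")
  generate_maf(fixture_config(seed = 53, n_genomes = 2, n_blocks = 4,
                              alphabet = "protein"), fp)
  ctp <- count_file_small(fp, 5, alphabet = "protein")
  dbp <- write_count_table_db(ctp, tempfile())
  expect_identical(nrow(dbp$index), 1L)
  expect_identical(dbp$alphabet, "protein")
  expect_same_counts(as_count_table(dbp), ctp)
})

test_that("read(write(records)) returns the written records exactly", {
  x <- make_db(seed = 54)
  db2 <- read_kmer_db(x$db$path)
  expect_identical(db_records(db2), db_records(x$db))
  expect_identical(db2$genomes$names, x$db$genomes$names)
  expect_identical(db2$k, x$db$k)
})

test_that("lookup agrees with a linear scan for present and absent k-mers", {
  x <- make_db(seed = 55)
  recs <- db_records(x$db)
  set.seed(551)
  for (km in sample(unique(recs$kmer), 20L)) {
    hit <- lookup_kmer(x$db, km)
    ref <- recs[recs$kmer == km, ]
    expect_identical(hit$genome, ref$genome)
    expect_identical(hit$count, ref$count)
  }
  absent <- setdiff(random_kmers(50, 12L), recs$kmer)
  for (km in absent) expect_identical(nrow(lookup_kmer(x$db, km)), 0L)
  expect_error(lookup_kmer(x$db, "ACGT"), class = "mafkmer_usage_error")
  expect_error(lookup_kmer(x$db, strrep("N", 12L)),
               class = "mafkmer_usage_error")
})

test_that("lookup is case- and U/T-insensitive like counting", {
  x <- make_db(seed = 56)
  recs <- db_records(x$db)
  km <- recs$kmer[1L]
  expect_identical(lookup_kmer(x$db, tolower(km)), lookup_kmer(x$db, km))
  expect_identical(lookup_kmer(x$db, chartr("T", "U", km)),
                   lookup_kmer(x$db, km))
})

test_that("the combined dump has one 'KMER name:count ...' line per k-mer in code order", {
  x <- make_db(seed = 57, n_blocks = 4)
  out <- tempfile(fileext = ".txt")
  dump_combined(x$db, out)
  lines <- readLines(out)
  recs <- db_records(x$db)
  kms <- unique(recs$kmer)
  expect_length(lines, length(kms))
  expect_identical(sub(" .*$", "", lines), kms)   # stored (code) order
  expect_true(all(grepl("^[ACGT]+( gen[0-9]+:[0-9]+)+$", lines)))
  # spot-check a full line against the records
  i <- which.max(table(recs$kmer)[kms])
  sub <- recs[recs$kmer == kms[i], ]
  expect_identical(lines[i], paste(kms[i], paste0(sub$genome, ":", sub$count,
                                                  collapse = " ")))
})

test_that("per-genome dumps conserve total count mass and cover every genome", {
  x <- make_db(seed = 58)
  dir <- tempfile("dumps_")
  paths <- dump_per_genome(x$db, dir)
  expect_identical(basename(paths), paste0(x$db$genomes$names, ".kmers"))
  expect_true(all(file.exists(paths)))
  mass <- sum(vapply(paths, function(p) {
    lines <- readLines(p)
    if (length(lines) == 0L) 0 else sum(as.numeric(sub("^\\S+ ", "", lines)))
  }, numeric(1)))
  expect_identical(mass, sum(db_records(x$db)$count))
})

test_that("corrupt or missing database files raise format/IO errors", {
  expect_error(read_kmer_db(tempfile("nope_")), class = "mafkmer_format_error")
  x <- make_db(seed = 59, n_blocks = 2)
  bad <- tempfile()
  file.copy(x$db$data_path, paste0(bad, ".mkc"))
  file.copy(x$db$idx_path, paste0(bad, ".mkc.idx"))
  con <- file(paste0(bad, ".mkc"), "r+b")
  writeBin(charToRaw("XXXX"), con)
  close(con)
  expect_error(read_kmer_db(bad), class = "mafkmer_format_error")
})

test_that("writing duplicate (prefix, remainder, genome) records is rejected", {
  gt <- genome_table("g1")
  recs <- data.table::data.table(prefix = c(0L, 0L), rem = c("AA", "AA"),
                                 gid = c(0L, 0L), count = c(1, 2))
  expect_error(write_database(recs, gt, 2, "dna", tempfile()),
               class = "mafkmer_contract_error")
})
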