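test_that("DNA encoding follows the A,C,G,T = 0..3 bit map and rejects ambiguity", {
  expect_equal(encode_dna("AAAAA")$value, 0)
  expect_equal(encode_dna("ACGT")$value, 27)       # 00 01 10 11
  expect_equal(encode_dna("ACGU")$value, 27)       # U treated as T
  expect_null(encode_dna("ACNGT"))
  expect_error(encode_dna(strrep("A", 65)), class = "mafkmer_usage_error")
})

test_that("protein encoding uses the fixed 25-symbol order and rejects outsiders", {
  expect_equal(encode_protein("AAAAA")$value, 0)
  expect_equal(encode_protein("ACD")$value, 34)    # (0<<10)|(1<<5)|2
  expect_null(encode_protein("AJ"))                # J not in the alphabet
  expect_null(encode_protein("A*"))
  expect_error(encode_protein(strrep("A", 26)), class = "mafkmer_usage_error")
})

test_that("decode inverts encode, including numeric codes", {
  expect_identical(decode_dna(27, k = 4), "ACGT")
  expect_identical(decode_dna(0, k = 3), "AAA")
  expect_identical(decode_kmer(encode_protein("MKWY")), "MKWY")
  set.seed(401)
  for (km in random_kmers(300, 20)) {
    expect_identical(decode_kmer(encode_dna(km)), km)
  }
  for (km in random_kmers(100, 25, mafkmer:::PROTEIN_ALPHABET)) {
    expect_identical(decode_kmer(encode_protein(km)), km)
  }
})

test_that("prefix/infix/suffix split matches the 10+10+2(k-10)-bit layout", {
  p <- split_parts(encode_dna("AAAAACCCCCGT"))
  expect_identical(p$prefix, 0L)
  expect_identical(p$infix, 341L)                  # binary 01 01 01 01 01
  expect_identical(p$suffix, 11)                   # binary 10 11
  expect_identical(split_parts(encode_dna(strrep("T", 11)))$prefix, 1023L)
  expect_error(split_parts(encode_dna("ACGTACGTAC")),
               class = "mafkmer_usage_error")
})

test_that("split and reassembly are inverse on random 30-mers", {
  set.seed(402)
  for (km in random_kmers(300, 30)) {
    code <- encode_dna(km)
    p <- split_parts(code)
    back <- assemble_code(p$prefix, c(mafkmer:::kmer_digits(
      substr(km, 6, 10), "dna"), p$suffix_digits))
    expect_identical(decode_kmer(back), km)
  }
})

test_that("record packing puts the genome ID in the 8 LSBs and round-trips", {
  expect_equal(pack_record(11, 2, 1)$key, 2818)
  r0 <- pack_record(0, 0, 5)
  expect_equal(r0$key, 0)
  expect_equal(r0$count, 5)
  expect_error(pack_record(1, 256, 1), class = "mafkmer_capacity_error")
  set.seed(403)
  for (i in 1:300) {
    rem <- floor(runif(1, 0, 2^40))
    gid <- sample(0:255, 1)
    cnt <- sample(1:10000, 1)
    pk <- pack_record(rem, gid, cnt)
    un <- unpack_record(pk$key, pk$count)
    expect_identical(un$remainder, rem)
    expect_identical(un$genome_id, gid)
    expect_identical(un$count, cnt)
  }
})

test_that("raw record packing round-trips for wide keys in both alphabets", {
  set.seed(404)
  for (k in c(6L, 15L, 28L, 59L)) {      # stored remainder widths (k - 5)
    rems <- random_kmers(50, k)
    gids <- sample(0:255, 50, replace = TRUE)
    counts <- sample(c(1:5, 70000L), 50, replace = TRUE)  # exercise >2 bytes
    r <- mafkmer:::pack_records_raw(rems, gids, counts, "dna")
    expect_length(r, 50L * (mafkmer:::key_width_bytes(k, "dna") + 4L))
    u <- mafkmer:::unpack_records_raw(r, k, "dna")
    expect_identical(u$rems, rems)
    expect_identical(u$gids, gids)
    expect_identical(as.integer(u$counts), as.integer(counts))
  }
  prems <- random_kmers(40, 25, mafkmer:::PROTEIN_ALPHABET)
  gids <- sample(0:255, 40, replace = TRUE)
  u <- mafkmer:::unpack_records_raw(
    mafkmer:::pack_records_raw(prems, gids, rep(1, 40), "protein"),
    25L, "protein")
  expect_identical(u$rems, prems)
  expect_identical(u$gids, gids)
})

test_that("encoding is strictly monotone in code-order string comparison", {
  set.seed(405)
  kms <- unique(random_kmers(400, 9))
  vals <- vapply(kms, function(km) encode_dna(km)$value, numeric(1))
  expect_identical(order(vals), order(kms))   # DNA: code order == ASCII order
  # protein: code order follows the alphabet rank, via the internal sort key
  pkms <- unique(random_kmers(400, 6, mafkmer:::PROTEIN_ALPHABET))
  pvals <- vapply(pkms, function(km) encode_protein(km)$value, numeric(1))
  expect_identical(order(pvals),
                   order(mafkmer:::codec_sortkey(pkms, "protein")))
})
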