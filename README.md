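# mafkmer

Per-genome k-mer counting directly in MAF (Multiple Alignment Format)
files, in R.

Multiple whole-genome alignments (UCSC multiz, Cactus, …) are distributed as
MAF files: stacks of alignment blocks, each holding one gapped sequence
fragment per genome. The usual route to k-mer statistics — export every
genome to FASTA, then run a k-mer counter per genome — multiplies disk usage
and loses the alignment context. `mafkmer` instead counts k-mers in a single
pass over the MAF itself, keeping one count per (k-mer, genome) pair, and can
exploit alignment-only metadata while counting: per-base quality (`q`) lines,
per-block alignment scores, and genome subsets.

## Model

- **Input**: MAF 1 text, plain or gzip-compressed, autodetected. `s` lines
  contribute sequence; `q` lines attach per-base qualities (`0`–`9`, `F` =
  "finished" above `9`, `.`/`-` = missing); `i`/`e` lines are parsed and
  retained but never counted. The genome of an `s` line is the `src` field up
  to the first dot (`hg38.chr1` → `hg38`).
- **Counting**: each `s` line is un-gapped and uppercased, then a width-k
  window slides along it. Windows containing symbols outside the alphabet
  (e.g. `N`) are dropped; `U` counts as `T`. There is no canonicalization —
  a k-mer and its reverse complement are distinct. Both DNA (k ≤ 64, 2 bits
  per base, `A<C<G<T`) and protein (k ≤ 25, 5 bits per residue, fixed
  25-symbol order `ACDEFGHIKLMNPQRSTVWYBZXUO`) alphabets are supported. At
  most 256 genomes per database (8-bit genome IDs).
- **Filters** (all ranges inclusive): genome-ID subset; per-window quality
  range (a window fails if any of its non-missing quality values falls
  outside `[min_q, max_q]`; sequences without a `q` line pass); per-block
  alignment-score range (blocks without a score fail an active range).
- **Engines**: for k ≤ 10 an in-memory hashmap engine; for DNA k > 10 a
  disk-based engine that routes occurrences to 1024 bins by the k-mer's
  10-bit 5-base *prefix*, partially sorts full bins on the *infix* (next 5
  bases), merges sorted runs into per-prefix packages, spills oversized
  packages to temporary files, and finally radix-sorts and aggregates each
  prefix. Reader/manager/sorter workers are deterministic work partitions:
  the output database is **byte-identical** for every worker count and
  threshold setting.
- **Storage**: a compact binary database (`<name>.mkc` + `<name>.mkc.idx`)
  with fixed-width records — packed k-mer code with the genome ID in the 8
  low bits, plus a 32-bit count — grouped into prefix sections whose byte
  offsets live in the index sidecar, so a single k-mer lookup touches only
  its section's byte range. Text dumps: one combined `KMER name:count …`
  file, or one `NAME.kmers` file per genome.
- **Analysis tools** (read-only on a database): `top_variance` (bounded
  min-heap selection of the k-mers with the highest across-genome count
  standard deviation), `genome_stats` (n/min/max/mean/median/sample
  variance/moment skewness g1 of one genome's counts), `filter_database`
  (boolean expressions such as `"hg38>2 && (mm10<1 || rn6=0)"` over
  per-genome counts, `&&` binding tighter than `||`), and `query_kmers`
  (exact list/file lookups, regular expressions, and the built-in
  G-quadruplex consensus `G{3,}N{1,7}` × 4).

A deterministic synthetic-MAF generator (`generate_maf`) and an intentionally
naive counting oracle (`oracle_counts`) ship with the package; every engine
is validated against the oracle in the test suite.

## Worked example

```r
library(mafkmer)

maf <- tempfile(fileext = ".maf")
generate_maf(fixture_config(seed = 42, n_genomes = 3, n_blocks = 6), maf)

# hashmap engine (k <= 10)
ct <- count_maf(maf, k = 4)
ct
#> <count_table dna k=4: 464 (k-mer, genome) entries, 238 distinct k-mers, 3 genomes>
#>      kmer   gid count
#> 1:   AAAA     0     1
#> 2:   AAAA     1     2
#> 3:   AAAC     0     1
#> ...

# disk engine (k > 10) writing a binary database
res <- count_maf(maf, k = 12, db_path = tempfile())
db <- attr(res, "db")
db
#> <kmer_db dna k=12: 478 records in 1024 section(s), 3 genomes>

lookup_kmer(db, "AAAACGGTAGCT")
#>    genome count
#> 1: gen001     1

# analysis tools on a database built from the k = 4 counts
db4 <- write_count_table_db(ct, tempfile())
top_variance(db4, 3)
#>      kmer      std
#> 1:   AGTA 2.645751
#> 2:   GTAT 2.516611
#> 3:   AGAG 2.309401

genome_stats(db4, "gen002")
#> <genome_stats gen002: n=159 min=1 max=5 mean=1.50943 median=1
#>  variance=0.55529 skewness=1.99303>

head(filter_database(db4, "gen001>2 && gen002=0"), 3)
#>      kmer   gid genome count
#> 1:   AATT     0 gen001     3
#> 2:   AATT     2 gen003     1
#> 3:   ATAC     0 gen001     3
```

The same surface is scriptable through the CLI wrapper `exec/mafkmer`:

```sh
mafkmer count --input aln.maf.gz --k 20 --out counts \
        --genome_ids hg38,mm10 --min_q_level 2 --max_q_level F
mafkmer dump  --db counts --out counts.txt
mafkmer tools variance --db counts --top 10
mafkmer tools filter   --db counts --expr 'hg38>0 && mm10=0'
mafkmer gen-fixture --seed 7 --out toy.maf --truth toy.tsv --k 4
```

Exit codes: 0 success, 2 usage, 3 parse, 4 capacity, 5 I/O or database
format, 1 anything else.

## Running the tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "mafkmer",
                               load_package = "installed")'
```

The suite covers the MAF parser, codec, both engines, the binary store, the
filters, the analysis tools, the CLI, and a property-based acceptance file
(engine/oracle equivalence across seeded corpora, byte-identity across
worker configurations, codec inverses on 10⁴ random k-mers, store
round-trips, and capacity guards).

## Reproducing results

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

generates a seeded fixture corpus, runs every component against the
brute-force oracle, and writes the computed quantities (distinct k-mer
counts, engine-agreement flags, byte-identity flag, lookup agreement
fraction, filter mass fractions, tool statistics) as JSON. All randomness
derives from `--seed`; rerunning with the same seed reproduces the file
exactly.

## Limitations

- Pure R: designed for correctness and desk-scale data, not for the
  multi-GB alignments the external-sorting design originally targets.
- "Threads" are deterministic sequential work partitions, not OS threads;
  the parallel structure is preserved (and its invariants tested) but wall
  clock does not scale with worker counts.
- No reverse-complement canonicalization, by design: occurrences are counted
  exactly as written in the alignment.
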