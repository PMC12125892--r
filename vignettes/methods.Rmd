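---
title: "mafkmer methods: counting k-mers per genome inside MAF alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mafkmer methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mafkmer)
```

## Problem and model

A MAF file stores a multiple whole-genome alignment as a sequence of blocks;
each block holds one gapped fragment per genome (`s` lines), optionally with
per-base quality strings (`q` lines) and a block alignment score. `mafkmer`
computes, in one pass over such a file, the number of occurrences of every
length-k substring *per genome*, where an occurrence is a window of the
un-gapped, uppercased `s`-line text.

The counting semantics are:

* every `s` line contributes, including the block's reference row;
* gaps (`-`) are removed before windowing, so k-mers may span gap columns;
* soft-masked lowercase counts (case is erased), `U` counts as `T`;
* a window containing any symbol outside the codec alphabet is dropped
  entirely (it neither counts nor splits the sequence);
* no reverse-complement canonicalization: `ACGT` and its complement are
  distinct keys;
* a genome's identity is the `src` field before the first `.`, and at most
  256 distinct genomes are allowed (counts are keyed by an 8-bit genome ID).

Three filters restrict which windows count, all with inclusive bounds:

* **genome subset** — only `s` lines of listed genomes;
* **quality range** — a window fails if any of its non-missing per-base
  quality values falls outside `[min_q, max_q]`. Symbols `0`–`9` map to
  0–9, `F` ("finished") to 10, and `.`/`-` to missing, which passes;
  sequences with no `q` line always pass;
* **score range** — applied per block; a block whose `a` line carries no
  score fails an *active* score filter (an unscored block cannot certify any
  score range).

## Codec and data layout

DNA uses 2 bits per base (`A`=0, `C`=1, `G`=2, `T`=3), so k ≤ 64; protein
uses 5 bits per residue over the fixed 25-symbol order
`ACDEFGHIKLMNPQRSTVWYBZXUO`, so k ≤ 25. A k-mer's integer code is its
base-|Σ| expansion in this order, carried internally as a digit vector, so
codes beyond 2^53 remain exact; a numeric `value` is materialized only when
it fits a double exactly (≤ 52 bits).

For DNA k > 10 the code splits into a 10-bit **prefix** (first 5 bases,
selecting one of 1024 bins), a 10-bit **infix** (next 5 bases), and a
2(k−10)-bit **suffix**. Stored records hold the *remainder* (infix‖suffix);
the prefix is implicit in the record's section, so the full k-mer is always
reconstructible.

A packed record is `(remainder_code << 8) | genome_id` in
`ceil((2(k−5)+8)/8)` little-endian bytes, followed by a 32-bit count. A
crucial invariant, exercised by the tests, is that comparing remainder
strings through `codec_sortkey()` (a `chartr` onto letters in alphabet rank
order) equals comparing integer codes — this is what lets `data.table`'s
radix string sort stand in for numeric sorting of arbitrarily wide codes,
and it is *not* plain lexicographic order for protein (e.g. `B` ranks after
`Y` in the codec).

## Engines

**Hashmap engine (k ≤ 10, and all protein).** Per-block windows accumulate
into a keyed table; chunk tables merge by pointwise addition. Because the
merge is associative and commutative and the genome table is built from the
whole file before counting, the result is independent of the partitioning —
the property that makes concurrent execution safe is asserted directly.

**Disk engine (DNA k > 10).** Modeled on external-memory k-mer sorting:
readers route occurrences to 1024 prefix bins; a bin reaching
`bin_threshold` is partially sorted on (infix, suffix, genome ID) and
compacted; per-prefix package managers concatenate sorted runs and spill
packages exceeding `package_threshold` to temporary files; finally each
prefix's spilled segments are loaded, fully sorted, aggregated, and written
at precomputed byte offsets. All "workers" are deterministic sequential
partitions of the work. The contract — a byte-identical database for every
(readers, managers, bin_threshold, package_threshold) — holds because (a)
per-prefix aggregation is order-independent, and (b) output offsets are
computed after all aggregation, per prefix, in fixed prefix order.

## Binary store

`<name>.mkc` holds a header (magic, version, alphabet, k, genome names in
first-seen ID order) followed by fixed-width records grouped by prefix
section, each section sorted strictly by packed key. `<name>.mkc.idx` lists
each section's absolute byte offset and record count (1024 sections for
split databases, 1 otherwise); offsets are non-decreasing and empty sections
carry the offset where their records would start. `lookup_kmer()` therefore
reads only one section's byte range and binary-searches it with the
genome-ID byte masked, giving random access without loading the database.

## Analysis tools and numerical choices

* `top_variance(db, T)` ranks k-mers by the *sample* standard deviation
  (denominator G−1) of the G-length count vector in which genomes lacking
  the k-mer contribute 0. Selection uses a bounded min-heap whose root is
  the worst retained element (lowest std, ties: highest code), so streaming
  order cannot affect the result; ties in the output are in ascending code
  order. With one genome the standard deviation is defined as 0.
* `genome_stats(db, g)` summarizes the counts of k-mers *present* in genome
  g: min, max, mean, median (mean of the two middle values for even n),
  sample variance (n−1 denominator, 0 for n = 1), and moment skewness
  g1 = m3/m2^{3/2} with population central moments, defined as 0 when
  m2 = 0. Accumulation is chunked via raw power sums (Σx, Σx², Σx³), and the
  tests assert chunk-size invariance; for the count magnitudes this package
  targets (small integers), raw power sums are numerically safe.
* `filter_database(db, expr)` evaluates `name op int` atoms (`<`, `>`, exact
  `=`) combined with `&&` over `||` (in that binding order) and parentheses,
  vectorized over a wide count matrix with absent genomes as zero columns.
* `query_kmers()` supports exact lookups (list or file), regular expressions
  with substring semantics, and the G-quadruplex consensus
  `G{3,}[ACGT]{1,7}` repeated — the pattern requires at least 15 bases, so
  it can only match for k ≥ 15.

## Synthetic fixtures and the oracle

`generate_maf(fixture_config(...))` produces MAF text that is byte-identical
for a given seed (the caller's RNG state is saved and restored) and
exercises the features that drive the counting semantics: multiple genomes
per block, gap columns, soft-masked lowercase, ambiguous symbols (`N`, or
`*` for protein — `X` is *inside* the protein alphabet), `q` lines with the
full symbol range including `F`, missing alignment scores, and minus
strands. It is deliberately **not** biologically realistic: bases are i.i.d.
uniform, there is no substitution model or phylogeny, coordinates are
arbitrary, and blocks are mutually independent. That is sufficient — and
preferable — for validation, because ground truth must be computable by
inspection.

`oracle_counts()` is the acceptance authority: a naive loop using plain
`substr` slicing and an environment as a nested map, sharing only the MAF
parser with the engines. Every engine result in the test suite is compared
against it exactly.

## Open design choices

* **Sequential determinism instead of OS threads.** R offers no shared-memory
  threading; the reader/manager/sorter structure is preserved as
  deterministic work partitions so the design's central invariant
  (byte-identical output under any parallel configuration) is testable,
  while wall clock does not scale.
* **Digit-vector codes.** 128-bit integers are unavailable; digit vectors
  plus the sort-key equivalence give exact arithmetic and exact ordering for
  k up to 64.
* **`data.table` for sorting/aggregation.** The partial sort, merge, and
  final aggregation map naturally onto radix-sorted table operations; the
  package treats them as the sorting primitive rather than reimplementing
  external sorting below the bin/package level.
* **Tool shape, not model shape.** The package is a counting tool with a
  database artifact, so its API is verb-based (`count_maf`, `lookup_kmer`,
  `top_variance`) rather than a fit/predict estimator idiom.

## Limitations

* Desk-scale by construction: the whole MAF's block list is materialized in
  memory before counting; only the k-mer record stream is external.
* Counts saturate nothing: counts are stored as 32-bit unsigned in the
  database, and the engines assume they fit.
* `e`/`i` lines are parsed but carry no counting semantics; alignment
  columns are not used beyond per-base qualities (no column-wise
  conservation statistics).
* No canonicalization option and no minimizer/streaming index; lookups are
  exact or regex-over-records only.
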