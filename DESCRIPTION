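Package: mafkmer
Title: K-mer Counting and Analysis for Multiple Alignment Format Files
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Counts per-genome k-mer occurrences directly in Multiple
    Alignment Format (MAF) files, for nucleotide and amino-acid alignments,
    without converting to FASTA. Provides a streaming MAF parser (plain or
    gzip-compressed input), a hashmap counting engine for small k, a
    disk-based engine for large k built on prefix binning, partial sorting
    on the infix, package merging with threshold-triggered spilling and a
    final per-prefix radix sort, a binary k-mer database with a per-prefix
    byte-offset index for random access, MAF-aware filters (genome subsets,
    per-base quality ranges, alignment-score ranges), and downstream tools:
    standard-deviation ranking of k-mers across genomes, per-genome count
    statistics, boolean-expression filtering of the database, and exact,
    list, file, regular-expression and G-quadruplex consensus queries. A
    deterministic synthetic-MAF generator and a brute-force counting oracle
    support end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
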