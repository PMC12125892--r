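# Deterministic synthetic-MAF generator with known ground truth, plus the
# brute-force counting oracle. The generator emulates the structural features
# that drive the counting semantics — multiple genomes per block, gaps,
# soft-masked lowercase, ambiguous bases, q lines (including 'F'), optional
# alignment scores, mixed strands — with no biological realism (no
# substitution model, no phylogeny).

#' Describe a synthetic MAF fixture
#'
#' @param seed Integer seed; generation is fully reproducible from it.
#' @param n_genomes Number of genomes (<= 256).
#' @param n_blocks Number of alignment blocks.
#' @param block_len Two-element range of alignment column counts.
#' @param gap_prob Per-column, per-genome probability of a gap.
#' @param lower_prob Probability that a base is written soft-masked
#'   (lowercase); counting uppercases, so these still count.
#' @param ambig_prob Probability of a symbol outside the codec alphabet (`N`
#'   for DNA, `*` for protein); windows spanning one are dropped.
#' @param q_prob Probability that an `s` line carries a `q` line.
#' @param q_levels,q_weights Quality symbols and their sampling weights.
#' @param score_range Uniform range for alignment scores.
#' @param missing_score_prob Probability that a block's `a` line has no score.
#' @param minus_prob Probability of a minus-strand `s` line.
#' @param alphabet `"dna"` or `"protein"`.
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(seed = 1L, n_genomes = 4L, n_blocks = 10L,
                           block_len = c(30L, 80L), gap_prob = 0.10,
                           lower_prob = 0.05, ambig_prob = 0.02,
                           q_prob = 0.5,
                           q_levels = c(as.character(0:9), "F"),
                           q_weights = c(rep(1, 10), 3),
                           score_range = c(-100, 10000),
                           missing_score_prob = 0.15,
                           minus_prob = 0.3,
                           alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (n_genomes < 1L || n_genomes > 256L) {
    usage_error("n_genomes must be in 1..256")
  }
  if (n_blocks < 0L) usage_error("n_blocks must be >= 0")
  if (length(block_len) != 2L || block_len[1] < 1L ||
      block_len[2] < block_len[1]) {
    usage_error("block_len must be a valid range with minimum >= 1")
  }
  probs <- c(gap_prob, lower_prob, ambig_prob, q_prob, missing_score_prob,
             minus_prob)
  if (any(probs < 0 | probs > 1)) usage_error("probabilities must be in [0, 1]")
  structure(list(seed = as.integer(seed), n_genomes = as.integer(n_genomes),
                 n_blocks = as.integer(n_blocks),
                 block_len = as.integer(block_len), gap_prob = gap_prob,
                 lower_prob = lower_prob, ambig_prob = ambig_prob,
                 q_prob = q_prob, q_levels = q_levels, q_weights = q_weights,
                 score_range = score_range,
                 missing_score_prob = missing_score_prob,
                 minus_prob = minus_prob, alphabet = alphabet),
            class = "fixture_config")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    get(".Random.seed", envir = .GlobalEnv)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
        rm(".Random.seed", envir = .GlobalEnv)
      }
    } else assign(".Random.seed", old, envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic MAF file with known structure
#'
#' Byte-identical output for the same `fixture_config`; the generated text
#' always parses cleanly with [read_maf()].
#'
#' @param config A [fixture_config()].
#' @param path Optional output file; when given, the text is written there
#'   (and the path returned invisibly).
#' @return Character vector of MAF lines (or `path`, invisibly).
#' @export
generate_maf <- function(config, path = NULL) {
  stopifnot(inherits(config, "fixture_config"))
  syms <- if (config$alphabet == "dna") DNA_ALPHABET
          else PROTEIN_ALPHABET[1:20]          # standard residues only
  # '*' (stop) is outside the 25-symbol protein alphabet, unlike 'X'
  ambig <- if (config$alphabet == "dna") "N" else "*"
  genomes <- sprintf("gen%03d", seq_len(config$n_genomes))
  lines <- with_seed(config$seed, {
    out <- c("##maf version=1 scoring=synthetic", "")
    for (b in seq_len(config$n_blocks)) {
      ncol <- sample(config$block_len[1]:config$block_len[2], 1L)
      a_line <- if (stats::runif(1) < config$missing_score_prob) "a"
                else sprintf("a score=%.1f",
                             stats::runif(1, config$score_range[1],
                                          config$score_range[2]))
      out <- c(out, a_line)
      for (g in seq_len(config$n_genomes)) {
        is_gap <- stats::runif(ncol) < config$gap_prob
        if (all(is_gap)) is_gap[sample.int(ncol, 1L)] <- FALSE
        chars <- ifelse(is_gap, "-",
                        ifelse(stats::runif(ncol) < config$ambig_prob, ambig,
                               sample(syms, ncol, replace = TRUE)))
        lower <- !is_gap & stats::runif(ncol) < config$lower_prob
        chars[lower] <- tolower(chars[lower])
        size <- sum(!is_gap)
        start <- sample.int(1000000L, 1L) - 1L
        strand <- if (stats::runif(1) < config$minus_prob) "-" else "+"
        src <- sprintf("%s.chr%d", genomes[g], sample.int(5L, 1L))
        out <- c(out, sprintf("s %s %d %d %s %d %s", src, start, size, strand,
                              2000000L, paste0(chars, collapse = "")))
        if (stats::runif(1) < config$q_prob) {
          q <- sample(config$q_levels, ncol, replace = TRUE,
                      prob = config$q_weights)
          q[is_gap] <- "-"
          out <- c(out, sprintf("q %s %s", src, paste0(q, collapse = "")))
        }
      }
      out <- c(out, "")
    }
    out
  })
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(path))
  }
  lines
}

#' Brute-force reference counts for a MAF input
#'
#' An intentionally naive single pass — plain string slicing, one window at a
#' time, nested-map accumulation — sharing nothing with the counting engines
#' beyond the MAF parser. Serves as the independent authority for engine
#' verification.
#'
#' @param maf A file path, or a character vector of MAF lines.
#' @param k K-mer length.
#' @param spec A [filter_spec()].
#' @param alphabet `"dna"` or `"protein"`.
#' @return A `count_table`.
#' @export
oracle_counts <- function(maf, k, spec = filter_spec(), alphabet = "dna") {
  k <- check_k(k, alphabet)
  path <- if (length(maf) == 1L && file.exists(maf) && !dir.exists(maf)) {
    maf
  } else {
    tmp <- tempfile(fileext = ".maf")
    writeLines(maf, tmp)
    tmp
  }
  blocks <- read_maf(path)
  gt <- build_genome_table(blocks)
  syms <- alphabet_symbols(alphabet)
  acc <- new.env(parent = emptyenv())
  q_active <- !is.null(spec$min_q) || !is.null(spec$max_q)
  a_active <- !is.null(spec$min_a) || !is.null(spec$max_a)
  lo_q <- spec$min_q %||% 0L
  hi_q <- spec$max_q %||% 10L

  for (blk in blocks) {
    if (a_active) {
      if (is.na(blk$score)) next
      if (!is.null(spec$min_a) && blk$score < spec$min_a) next
      if (!is.null(spec$max_a) && blk$score > spec$max_a) next
    }
    for (i in seq_along(blk$sequences)) {
      g <- sub("\\..*$", "", blk$sequences[[i]]$src)
      if (!is.null(spec$genome_ids) && !(g %in% spec$genome_ids)) next
      aligned <- strsplit(blk$sequences[[i]]$text, "")[[1]]
      keep <- aligned != "-"
      s <- toupper(paste0(aligned[keep], collapse = ""))
      if (alphabet == "dna") s <- chartr("U", "T", s)
      qv <- NULL
      if (!is.null(blk$qualities[[i]])) {
        qc <- strsplit(blk$qualities[[i]]$qualities, "")[[1]][keep]
        qv <- suppressWarnings(as.integer(qc))
        qv[qc %in% c("F", "f")] <- 10L
      }
      n <- nchar(s)
      if (n < k) next
      for (st in 1:(n - k + 1L)) {
        km <- substr(s, st, st + k - 1L)
        chars <- strsplit(km, "")[[1]]
        if (!all(chars %in% syms)) next
        if (q_active && !is.null(qv)) {
          w <- qv[st:(st + k - 1L)]
          w <- w[!is.na(w)]
          if (length(w) && (any(w < lo_q) || any(w > hi_q))) next
        }
        key <- paste0(km, "\r", g)
        acc[[key]] <- (acc[[key]] %||% 0) + 1
      }
    }
  }
  keys <- ls(acc)
  if (length(keys) == 0L) return(count_table(k, gt, alphabet))
  parts <- strsplit(keys, "\r", fixed = TRUE)
  dt <- data.table::data.table(
    kmer = vapply(parts, `[[`, character(1), 1L),
    gid = genome_id(gt, vapply(parts, `[[`, character(1), 2L)),
    count = vapply(keys, function(key) acc[[key]], numeric(1),
                   USE.NAMES = FALSE))
  count_table(k, gt, alphabet, counts = dt)
}
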