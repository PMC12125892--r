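# MAF-specific inclusion rules applied before any k-mer is counted:
# genome subsets, per-base quality ranges (q lines) and per-block
# alignment-score ranges (a lines). All ranges are inclusive at both ends.

#' Describe the active MAF-level filters
#'
#' @param genome_ids Optional character vector of genome names to keep;
#'   `NULL` keeps all genomes.
#' @param min_q,max_q Optional per-base quality bounds, integers in 0--10
#'   (`'F'` = finished maps to 10; see [ungap()]). A window is counted only
#'   when every base with a quality value lies in `[min_q, max_q]`.
#' @param min_a,max_a Optional alignment-score bounds (reals). When either is
#'   set, blocks without a score are excluded: a missing score means the
#'   alignment quality is unknown, so such a block cannot be shown to lie in
#'   the requested range. (Sequences without a `q` line, by contrast, pass an
#'   active quality filter — missing `q` lines are the norm in most MAFs.)
#' @return A `filter_spec` object.
#' @examples
#' filter_spec(genome_ids = c("hg38", "mm10"), min_q = 5, max_q = 10)
#' @export
filter_spec <- function(genome_ids = NULL, min_q = NULL, max_q = NULL,
                        min_a = NULL, max_a = NULL) {
  chk_q <- function(q, what) {
    if (is.null(q)) return(NULL)
    if (is.character(q)) q <- q_symbol_value(toupper(q))
    if (length(q) != 1L || is.na(q) || q < 0 || q > 10) {
      usage_error(sprintf("%s must be in 0..9 or 'F'", what))
    }
    as.integer(q)
  }
  min_q <- chk_q(min_q, "min_q")
  max_q <- chk_q(max_q, "max_q")
  if (!is.null(min_q) && !is.null(max_q) && min_q > max_q) {
    usage_error("min_q exceeds max_q")
  }
  if (!is.null(min_a) && !is.null(max_a) && min_a > max_a) {
    usage_error("min_a exceeds max_a")
  }
  structure(list(genome_ids = genome_ids,
                 min_q = min_q, max_q = max_q,
                 min_a = if (is.null(min_a)) NULL else as.numeric(min_a),
                 max_a = if (is.null(max_a)) NULL else as.numeric(max_a)),
            class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  act <- character(0)
  if (!is.null(x$genome_ids)) {
    act <- c(act, paste0("genomes={", paste(x$genome_ids, collapse = ","), "}"))
  }
  if (!is.null(x$min_q) || !is.null(x$max_q)) {
    act <- c(act, sprintf("q=[%s,%s]", x$min_q %||% 0, x$max_q %||% 10))
  }
  if (!is.null(x$min_a) || !is.null(x$max_a)) {
    act <- c(act, sprintf("a=[%s,%s]", x$min_a %||% "-Inf", x$max_a %||% "Inf"))
  }
  cat("<filter_spec:", if (length(act)) paste(act, collapse = " ")
      else "no filters", ">\n")
  invisible(x)
}

has_q_filter <- function(spec) !is.null(spec$min_q) || !is.null(spec$max_q)
has_a_filter <- function(spec) !is.null(spec$min_a) || !is.null(spec$max_a)

#' Does an alignment block pass the score filter?
#'
#' @param block A `maf_block`.
#' @param spec A `filter_spec`.
#' @return `TRUE` iff no score filter is active, or the block carries a score
#'   inside the (inclusive) range. Score-less blocks fail an active filter.
#' @export
block_passes <- function(block, spec) {
  if (!has_a_filter(spec)) return(TRUE)
  s <- block$score
  if (is.null(s) || is.na(s)) return(FALSE)
  (is.null(spec$min_a) || s >= spec$min_a) &&
    (is.null(spec$max_a) || s <= spec$max_a)
}

#' Is a genome selected by the filter?
#'
#' @param genome Character vector of genome names.
#' @param spec A `filter_spec`.
#' @return Logical vector: `TRUE` iff no genome subset is active or the
#'   genome belongs to it.
#' @export
sequence_selected <- function(genome, spec) {
  if (is.null(spec$genome_ids)) rep(TRUE, length(genome))
  else genome %in% spec$genome_ids
}

#' Does one k-window pass the quality filter?
#'
#' @param qualities Integer vector of per-base quality values for the window
#'   (length k); `NA` entries (no value) always pass.
#' @param spec A `filter_spec`.
#' @return `TRUE` iff no quality filter is active or every valued base lies
#'   in the inclusive range.
#' @export
window_quality_ok <- function(qualities, spec) {
  if (!has_q_filter(spec)) return(TRUE)
  q <- qualities[!is.na(qualities)]
  all((is.null(spec$min_q) | q >= (spec$min_q %||% 0L)) &
        (is.null(spec$max_q) | q <= (spec$max_q %||% 10L)))
}

# Warn once about requested genomes never seen in the file.
warn_missing_genomes <- function(spec, gt) {
  if (is.null(spec$genome_ids)) return(invisible())
  missing <- setdiff(spec$genome_ids, gt$names)
  if (length(missing)) {
    warning(sprintf("requested genome(s) not present in the MAF: %s",
                    paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible()
}

## ---- shared window scanner ------------------------------------------------
## Both counting engines extract accepted k-windows through this routine:
## ungap, uppercase, slide a width-k window, drop windows spanning symbols
## outside the alphabet, and apply the per-base quality rule.

# Returns a data.table(kmer, genome) of accepted windows of one block,
# or NULL. All s lines contribute, including the reference.
block_windows <- function(block, k, spec, alphabet = "dna") {
  if (!block_passes(block, spec)) return(NULL)
  syms <- alphabet_symbols(alphabet)
  out <- vector("list", length(block$sequences))
  for (i in seq_along(block$sequences)) {
    sl <- block$sequences[[i]]
    g <- extract_genome_id(sl$src)
    if (!sequence_selected(g, spec)) next
    ug <- ungap(sl, block$qualities[[i]])
    s <- ug$seq
    if (alphabet == "dna") s <- chartr("U", "T", s)
    n <- nchar(s)
    if (n < k) next
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    bad <- as.integer(!(chars %in% syms))
    if (has_q_filter(spec) && !is.null(ug$qual)) {
      q <- ug$qual
      oor <- !is.na(q) &
        ((q < (spec$min_q %||% 0L)) | (q > (spec$max_q %||% 10L)))
      bad <- bad + as.integer(oor)
    }
    cs <- c(0L, cumsum(bad))
    starts <- seq_len(n - k + 1L)
    ok <- (cs[starts + k] - cs[starts]) == 0L
    if (!any(ok)) next
    st <- starts[ok]
    out[[i]] <- data.table::data.table(kmer = substring(s, st, st + k - 1L),
                                       genome = g)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) return(NULL)
  data.table::rbindlist(out)
}
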