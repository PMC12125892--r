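# MAF parsing: streaming block reader for plain or gzip-compressed files.
#
# The UCSC MAF dialect is line-oriented: alignment blocks start with an "a"
# line (optionally carrying key=value attributes such as score=), followed by
# one "s" line per aligned sequence, each optionally followed by a "q"
# (per-base quality) line; "i" and "e" lines carry context/gap annotations and
# are retained verbatim but never contribute k-mers.

#' Open a streaming reader over a MAF file
#'
#' Returns an iterator over alignment blocks. Gzip compression is detected
#' from the file's magic bytes (not its extension) and decompressed on the
#' fly; no extracted copy is written. Blank lines, `#` comments and `track`
#' lines are skipped.
#'
#' @param path Path to a MAF file, plain or gzip-compressed.
#' @return An object of class `maf_stream` with elements `next_block`
#'   (a function returning the next `maf_block`, or `NULL` at end of file)
#'   and `close`.
#' @seealso [read_maf()] to materialize all blocks at once.
#' @export
open_maf_stream <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path) ||
      dir.exists(path)) {
    io_error(sprintf("cannot open MAF input '%s'", paste(path, collapse = ",")))
  }
  con <- gzfile(path)   # reads plain files too; gzip sniffed from magic bytes
  ok <- tryCatch({ open(con, "rt"); TRUE }, error = function(e) FALSE)
  if (!ok) io_error(sprintf("cannot open MAF input '%s'", path))

  lineno <- 0L
  pushed <- NULL
  finished <- FALSE

  read_line <- function() {
    if (!is.null(pushed)) {
      l <- pushed
      pushed <<- NULL
      return(l)
    }
    l <- readLines(con, n = 1L, warn = FALSE)
    if (length(l) == 0L) return(NULL)
    lineno <<- lineno + 1L
    l
  }
  push_back <- function(l) pushed <<- l

  finish <- function() {
    if (!finished) {
      finished <<- TRUE
      try(close(con), silent = TRUE)
    }
  }

  parse_a_line <- function(t) {
    fields <- strsplit(t, "[ \t]+")[[1]][-1L]
    score <- NA_real_
    for (f in fields) {
      kv <- strsplit(f, "=", fixed = TRUE)[[1]]
      if (length(kv) == 2L && kv[1] == "score") {
        score <- suppressWarnings(as.numeric(kv[2]))
        if (is.na(score)) {
          parse_error(sprintf("line %d: unparseable score '%s'", lineno, kv[2]))
        }
      }
    }
    score
  }

  parse_s_line <- function(t) {
    f <- strsplit(t, "[ \t]+")[[1]]
    if (length(f) != 7L) {
      parse_error(sprintf(
        "line %d: 's' line has %d fields, expected 7", lineno, length(f)))
    }
    start <- suppressWarnings(as.numeric(f[3]))
    size <- suppressWarnings(as.numeric(f[4]))
    src_size <- suppressWarnings(as.numeric(f[6]))
    if (is.na(start) || is.na(size) || is.na(src_size)) {
      parse_error(sprintf("line %d: non-numeric coordinate on 's' line", lineno))
    }
    if (!(f[5] %in% c("+", "-"))) {
      parse_error(sprintf("line %d: strand must be '+' or '-'", lineno))
    }
    list(src = f[2], start = start, size = size, strand = f[5],
         src_size = src_size, text = f[7])
  }

  next_block <- function() {
    if (finished) return(NULL)
    # advance to the next "a" line
    repeat {
      l <- read_line()
      if (is.null(l)) {
        finish()
        return(NULL)
      }
      t <- trimws(l, which = "right")
      if (t == "" || grepl("^\\s*$", t)) next
      if (startsWith(t, "#") || startsWith(t, "track")) next
      if (grepl("^a( |$)", t)) break
      parse_error(sprintf(
        "line %d: expected 'a' line, got '%s' (not MAF content?)",
        lineno, substr(t, 1L, 40L)))
    }
    score <- parse_a_line(t)
    sequences <- list()
    qualities <- list()
    info <- character(0)

    repeat {
      l <- read_line()
      if (is.null(l)) break
      t <- trimws(l, which = "right")
      if (t == "" || grepl("^\\s*$", t)) break            # blank line ends block
      if (grepl("^a( |$)", t)) { push_back(l); break }    # next block
      if (startsWith(t, "#")) next
      code <- substr(t, 1L, 1L)
      if (code == "s") {
        sl <- parse_s_line(t)
        sequences[[length(sequences) + 1L]] <- sl
        qualities[length(sequences)] <- list(NULL)
      } else if (code == "q") {
        f <- strsplit(t, "[ \t]+")[[1]]
        if (length(f) != 3L) {
          parse_error(sprintf("line %d: 'q' line has %d fields, expected 3",
                              lineno, length(f)))
        }
        if (length(sequences) == 0L) {
          parse_error(sprintf("line %d: 'q' line before any 's' line", lineno))
        }
        i <- length(sequences)
        if (nchar(f[3]) != nchar(sequences[[i]]$text)) {
          parse_error(sprintf(
            "line %d: quality string length %d != aligned sequence length %d",
            lineno, nchar(f[3]), nchar(sequences[[i]]$text)))
        }
        qualities[[i]] <- list(src = f[2], qualities = f[3])
      } else if (code %in% c("i", "e")) {
        info <- c(info, t)                                # retained, never counted
      } else {
        parse_error(sprintf("line %d: unknown MAF line type '%s'", lineno, code))
      }
    }

    if (length(sequences) == 0L) {
      parse_error("alignment block with no 's' lines")
    }
    widths <- vapply(sequences, function(s) nchar(s$text), integer(1))
    if (length(unique(widths)) != 1L) {
      parse_error(sprintf(
        "alignment block ending at line %d: unequal column counts (%s)",
        lineno, paste(unique(widths), collapse = ",")))
    }
    # size consistency is advisory: real-world MAFs contain inconsistencies
    for (s in sequences) {
      ng <- nchar(gsub("-", "", s$text, fixed = TRUE))
      if (ng != s$size) {
        warning(sprintf(
          "s line '%s': %d non-gap characters but size field %d",
          s$src, ng, s$size), call. = FALSE)
      }
    }
    structure(list(score = score, sequences = sequences, qualities = qualities,
                   info = info),
              class = "maf_block")
  }

  structure(list(next_block = next_block, close = finish), class = "maf_stream")
}

#' Read all alignment blocks of a MAF file
#'
#' @inheritParams open_maf_stream
#' @return A list of `maf_block` objects, in file order (possibly empty).
#' @examples
#' maf <- tempfile(fileext = ".maf")
#' writeLines(c("a score=10.0",
#'              "s hg38.chr1 0 4 + 1000 AC-GT",
#'              "s mm10.chr2 5 5 - 2000 ACGGT"), maf)
#' length(read_maf(maf))
#' @export
read_maf <- function(path) {
  st <- open_maf_stream(path)
  on.exit(st$close())
  blocks <- list()
  repeat {
    b <- st$next_block()
    if (is.null(b)) break
    blocks[[length(blocks) + 1L]] <- b
  }
  blocks
}

#' Derive the genome name from a MAF `src` field
#'
#' MAF `s` lines use the UCSC `database.chromosome` convention; the genome
#' name is the part before the first dot. A `src` with no dot is returned
#' unchanged.
#'
#' @param src Character vector of `src` fields.
#' @return Character vector of genome names.
#' @examples
#' extract_genome_id(c("hg38.chr1", "scaffold_12", "panTro6.chrUn.scaf17"))
#' @export
extract_genome_id <- function(src) {
  if (length(src) == 0L) return(character(0))
  if (any(is.na(src) | !nzchar(src))) parse_error("empty 'src' field")
  sub("\\..*$", "", src)
}

#' Remove gaps from an aligned sequence (and its quality string)
#'
#' Strips `-` columns, uppercases the sequence, and, when a quality line is
#' supplied, returns per-base quality values aligned index-for-index with the
#' ungapped sequence. Quality symbols map `'0'`--`'9'` to 0--9 and `'F'`
#' (finished) to 10; `'.'` (missing) yields `NA`.
#'
#' @param line A sequence line (list with at least `text`), or a bare string.
#' @param quality Optional quality line (list with `qualities`), or a bare
#'   string of the same length as the aligned text.
#' @return A list with `seq` (ungapped, uppercased string) and `qual`
#'   (integer vector or `NULL`).
#' @examples
#' ungap("AC-GT", "99-F1")
#' @export
ungap <- function(line, quality = NULL) {
  text <- if (is.list(line)) line$text else line
  qtext <- if (is.null(quality)) NULL
           else if (is.list(quality)) quality$qualities else quality
  if (!is.null(qtext) && nchar(qtext) != nchar(text)) {
    abort(sprintf("quality length %d != sequence length %d",
                  nchar(qtext), nchar(text)), "mafkmer_consistency_error")
  }
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  keep <- chars != "-"
  seq <- toupper(paste0(chars[keep], collapse = ""))
  qual <- NULL
  if (!is.null(qtext)) {
    qchars <- strsplit(qtext, "", fixed = TRUE)[[1]][keep]
    qual <- q_symbol_value(qchars)
  }
  list(seq = seq, qual = qual)
}

# '0'-'9' -> 0..9, 'F' -> 10 (finished ranks above 9 so a q range can express
# "finished bases only"), '.'/'-' -> NA (no value).
q_symbol_value <- function(chars) {
  v <- match(chars, as.character(0:9)) - 1L
  v[chars %in% c("F", "f")] <- 10L
  v
}

#' Build the genome name/ID table for a set of alignment blocks
#'
#' Assigns each distinct genome (per [extract_genome_id()]) a small integer
#' ID in first-seen order over the `s` lines. IDs are stored in an 8-bit
#' field, so at most 256 genomes are supported.
#'
#' @param blocks A list of `maf_block` objects (or a `maf_stream`).
#' @return A `genome_table` object.
#' @export
build_genome_table <- function(blocks) {
  if (inherits(blocks, "maf_stream")) {
    acc <- character(0)
    repeat {
      b <- blocks$next_block()
      if (is.null(b)) break
      acc <- c(acc, vapply(b$sequences, function(s) s$src, character(1)))
    }
    srcs <- acc
  } else {
    srcs <- unlist(lapply(blocks, function(b)
      vapply(b$sequences, function(s) s$src, character(1))))
  }
  names <- unique(extract_genome_id(srcs %||% character(0)))
  genome_table(names)
}

#' Construct a genome table from an ordered vector of names
#'
#' @param names Character vector of distinct genome names; position in the
#'   vector determines the ID (`names[1]` gets ID 0).
#' @return A `genome_table` object.
#' @export
genome_table <- function(names = character(0)) {
  names <- as.character(names)
  if (anyDuplicated(names)) abort("genome names must be distinct",
                                  "mafkmer_usage_error")
  if (length(names) > 256L) {
    capacity_error(sprintf(
      "%d distinct genomes exceed the 256 supported by the 8-bit genome-ID field",
      length(names)))
  }
  structure(list(names = names), class = "genome_table")
}

#' Look up genome IDs by name
#'
#' @param gt A `genome_table`.
#' @param name Character vector of genome names.
#' @return Integer IDs in `[0, 255]`; error for unknown names.
#' @export
genome_id <- function(gt, name) {
  i <- match(name, gt$names)
  if (anyNA(i)) {
    abort(sprintf("unknown genome name(s): %s",
                  paste(name[is.na(i)], collapse = ", ")),
          "mafkmer_lookup_error")
  }
  i - 1L
}

#' @export
print.genome_table <- function(x, ...) {
  cat(sprintf("<genome_table: %d genomes>\n", length(x$names)))
  if (length(x$names)) {
    show <- utils::head(x$names, 10L)
    cat(paste(sprintf("  %d: %s", seq_along(show) - 1L, show), collapse = "\n"),
        "\n")
    if (length(x$names) > 10L) cat(sprintf("  ... %d more\n",
                                           length(x$names) - 10L))
  }
  invisible(x)
}

#' @export
print.maf_block <- function(x, ...) {
  cat(sprintf("<maf_block: %d sequences, %d columns, score=%s>\n",
              length(x$sequences), nchar(x$sequences[[1]]$text),
              if (is.na(x$score)) "NA" else format(x$score)))
  invisible(x)
}

# Partition a block list into n contiguous chunks at block boundaries.
# A block is never split, so per-chunk results are well defined.
partition_blocks <- function(blocks, n) {
  n <- max(1L, as.integer(n))
  if (length(blocks) == 0L) return(list())
  n <- min(n, length(blocks))
  idx <- sort(rep_len(seq_len(n), length(blocks)))
  unname(split(blocks, idx))
}
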