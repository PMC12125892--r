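# Downstream analysis over a binary k-mer database: standard-deviation
# ranking across genomes, per-genome count statistics, boolean-expression
# filtering, and exact / list / file / regex / G-quadruplex queries.
# Every tool is read-only on the database.

## ---- bounded min-heap -------------------------------------------------------
## Keeps the T best (std, code) pairs while streaming; the root is always the
## worst retained element (lowest std, ties: highest code), so a new element
## replaces the root iff it beats it.

heap_new <- function(capacity) {
  e <- new.env(parent = emptyenv())
  e$std <- numeric(capacity)
  e$key <- character(capacity)   # code-order sort key, for ties
  e$kmer <- character(capacity)
  e$n <- 0L
  e$capacity <- capacity
  e
}

# is element a "worse" than b? (lower std, ties broken so that the larger
# code is worse — the result keeps ascending-code ties)
heap_lt <- function(h, ai, bs, bk) {
  h$std[ai] < bs || (h$std[ai] == bs && h$key[ai] > bk)
}

heap_swap <- function(h, i, j) {
  tmp <- h$std[i]; h$std[i] <- h$std[j]; h$std[j] <- tmp
  tmp <- h$key[i]; h$key[i] <- h$key[j]; h$key[j] <- tmp
  tmp <- h$kmer[i]; h$kmer[i] <- h$kmer[j]; h$kmer[j] <- tmp
}

heap_sift_down <- function(h, i) {
  repeat {
    l <- 2L * i; r <- l + 1L; m <- i
    if (l <= h$n && heap_lt(h, l, h$std[m], h$key[m])) m <- l
    if (r <= h$n && heap_lt(h, r, h$std[m], h$key[m])) m <- r
    if (m == i) break
    heap_swap(h, i, m)
    i <- m
  }
}

heap_offer <- function(h, std, key, kmer) {
  if (h$n < h$capacity) {
    h$n <- h$n + 1L
    i <- h$n
    h$std[i] <- std; h$key[i] <- key; h$kmer[i] <- kmer
    while (i > 1L) {                       # sift up
      p <- i %/% 2L
      if (heap_lt(h, i, h$std[p], h$key[p])) {
        heap_swap(h, i, p)
        i <- p
      } else break
    }
  } else if (heap_lt(h, 1L, std, key)) {   # beats the worst retained
    h$std[1L] <- std; h$key[1L] <- key; h$kmer[1L] <- kmer
    heap_sift_down(h, 1L)
  }
  invisible(h)
}

## ---- variance ranking -------------------------------------------------------

#' Rank k-mers by count standard deviation across genomes
#'
#' For every k-mer, the count vector spans all genomes in the database's
#' genome table (absent genome = count 0); its sample standard deviation
#' (denominator G-1; 0 when the table has a single genome) ranks the k-mer.
#' Selection uses a bounded min-heap of size `top`, streaming the database
#' prefix by prefix, so the result is independent of chunking. Ties are
#' broken by ascending k-mer code.
#'
#' @param db A `kmer_db`.
#' @param top Number of k-mers to return (positive).
#' @return `data.table(kmer, std)` in descending std, ascending code order.
#' @export
top_variance <- function(db, top) {
  if (length(top) != 1L || is.na(top) || top < 1 || top != floor(top)) {
    usage_error("top must be a positive integer")
  }
  G <- length(db$genomes$names)
  if (G < 1L) usage_error("database has no genomes")
  h <- heap_new(as.integer(top))
  for (p in db$index$prefix[db$index$count > 0L]) {
    recs <- db_records(db, p)
    stats <- recs[, list(s1 = sum(count), s2 = sum(count^2)), by = list(kmer)]
    # sample variance over the G-length vector, absent genomes contributing 0
    stats[, std := if (G == 1L) 0 else
      sqrt(pmax(0, (s2 - s1^2 / G) / (G - 1)))]
    stats[, sk := codec_sortkey(kmer, db$alphabet)]
    for (i in seq_len(nrow(stats))) {
      heap_offer(h, stats$std[i], stats$sk[i], stats$kmer[i])
    }
  }
  n <- h$n
  out <- data.table::data.table(kmer = h$kmer[seq_len(n)],
                                std = h$std[seq_len(n)],
                                sk = h$key[seq_len(n)])
  data.table::setorderv(out, c("std", "sk"), order = c(-1L, 1L))
  out[, sk := NULL]
  out[]
}

## ---- per-genome statistics --------------------------------------------------

#' Summary statistics of one genome's k-mer count distribution
#'
#' Statistics are over the multiset of counts of k-mers *present* in the
#' genome (a genome's distribution is over the k-mers it contains). The
#' median of an even-sized multiset is the mean of the two middle values;
#' variance uses the sample (n-1) denominator (0 when n = 1); skewness is the
#' moment coefficient g1 = m3 / m2^(3/2) with population central moments,
#' defined as 0 when m2 = 0. Data are processed in chunks of `chunk_size`
#' k-mers; the result equals the single-pass computation for every chunk
#' size.
#'
#' @param db A `kmer_db`.
#' @param genome Genome name (must be in the database's genome table).
#' @param chunk_size Records per processing chunk.
#' @return A `genome_stats` list: `genome`, `n`, `min`, `max`, `mean`,
#'   `median`, `variance`, `skewness`.
#' @export
genome_stats <- function(db, genome, chunk_size = 65536L) {
  gid_want <- genome_id(db$genomes, genome)   # errors on unknown genome
  chunk_size <- max(1L, as.integer(chunk_size))
  n <- 0; s1 <- 0; s2 <- 0; s3 <- 0
  mn <- Inf; mx <- -Inf
  values <- list()
  for (p in db$index$prefix[db$index$count > 0L]) {
    recs <- db_records(db, p)
    cnt <- recs$count[recs$gid == gid_want]
    if (length(cnt) == 0L) next
    for (i in seq(1L, length(cnt), by = chunk_size)) {
      x <- cnt[i:min(length(cnt), i + chunk_size - 1L)]
      n <- n + length(x)
      s1 <- s1 + sum(x); s2 <- s2 + sum(x^2); s3 <- s3 + sum(x^3)
      mn <- min(mn, x); mx <- max(mx, x)
      values[[length(values) + 1L]] <- x
    }
  }
  if (n == 0L) {
    return(structure(list(genome = genome, n = 0L, min = NA_real_,
                          max = NA_real_, mean = NA_real_, median = NA_real_,
                          variance = NA_real_, skewness = NA_real_),
                     class = "genome_stats"))
  }
  mean <- s1 / n
  m2 <- s2 / n - mean^2
  m3 <- s3 / n - 3 * mean * s2 / n + 2 * mean^3
  variance <- if (n > 1L) (s2 - s1^2 / n) / (n - 1) else 0
  skewness <- if (m2 > 0) m3 / m2^1.5 else 0
  structure(list(genome = genome, n = as.integer(n), min = mn, max = mx,
                 mean = mean, median = stats::median(unlist(values)),
                 variance = variance, skewness = skewness),
            class = "genome_stats")
}

#' @export
print.genome_stats <- function(x, ...) {
  cat(sprintf(paste0("<genome_stats %s: n=%d min=%g max=%g mean=%g ",
                     "median=%g variance=%g skewness=%g>\n"),
              x$genome, x$n, x$min, x$max, x$mean, x$median, x$variance,
              x$skewness))
  invisible(x)
}

## ---- boolean-expression filter ----------------------------------------------
## Grammar:  expr := term ('||' term)* ; term := factor ('&&' factor)* ;
##           factor := atom | '(' expr ')' ; atom := NAME op INT,
##           op in {<, >, =}. '&&' binds tighter than '||'.

#' Parse a count-filter expression
#'
#' @param text Expression such as `"hg38>2 && (mm10<1 || rn6=0)"`.
#' @return A `filter_expr` parse tree.
#' @export
parse_expr <- function(text) {
  src <- text
  pos <- 1L
  len <- nchar(text)
  err <- function(msg, at = pos) {
    parse_error(sprintf("expression parse error at position %d: %s (in '%s')",
                        at, msg, src))
  }
  skip_ws <- function() {
    while (pos <= len && substr(src, pos, pos) %in% c(" ", "\t")) pos <<- pos + 1L
  }
  peek <- function(n = 1L) substr(src, pos, pos + n - 1L)
  next_token <- function() {
    skip_ws()
    if (pos > len) return(list(type = "eof", at = pos))
    at <- pos
    c2 <- peek(2L)
    if (c2 == "&&" || c2 == "||") {
      pos <<- pos + 2L
      return(list(type = c2, at = at))
    }
    c1 <- peek()
    if (c1 %in% c("(", ")", "<", ">", "=")) {
      pos <<- pos + 1L
      return(list(type = c1, at = at))
    }
    m <- regmatches(substr(src, pos, len),
                    regexpr("^-?[0-9]+", substr(src, pos, len)))
    if (length(m) && nzchar(m)) {
      pos <<- pos + nchar(m)
      return(list(type = "int", value = as.numeric(m), at = at))
    }
    m <- regmatches(substr(src, pos, len),
                    regexpr("^[A-Za-z_][A-Za-z0-9_.]*", substr(src, pos, len)))
    if (length(m) && nzchar(m)) {
      pos <<- pos + nchar(m)
      return(list(type = "name", value = m, at = at))
    }
    err(sprintf("unexpected character '%s'", c1), at)
  }
  tok <- next_token()
  advance <- function() tok <<- next_token()

  parse_atom <- function() {
    if (tok$type == "(") {
      advance()
      e <- parse_or()
      if (tok$type != ")") err("expected ')'", tok$at)
      advance()
      return(e)
    }
    if (tok$type != "name") err("expected a genome name or '('", tok$at)
    name <- tok$value
    advance()
    if (!(tok$type %in% c("<", ">", "="))) {
      err("expected one of <, >, = after genome name", tok$at)
    }
    op <- tok$type
    advance()
    if (tok$type != "int") err(sprintf("expected an integer after '%s'", op),
                               tok$at)
    value <- tok$value
    advance()
    list(type = "atom", name = name, op = op, value = value)
  }
  parse_and <- function() {
    e <- parse_atom()
    while (tok$type == "&&") {
      advance()
      e <- list(type = "and", lhs = e, rhs = parse_atom())
    }
    e
  }
  parse_or <- function() {
    e <- parse_and()
    while (tok$type == "||") {
      advance()
      e <- list(type = "or", lhs = e, rhs = parse_and())
    }
    e
  }
  e <- parse_or()
  if (tok$type != "eof") err("trailing input", tok$at)
  structure(e, class = "filter_expr", text = src)
}

#' @export
print.filter_expr <- function(x, ...) {
  cat("<filter_expr:", deparse_expr(x), ">\n")
  invisible(x)
}

deparse_expr <- function(e) {
  switch(e$type,
         atom = sprintf("%s%s%s", e$name, e$op,
                        format(e$value, scientific = FALSE)),
         and = sprintf("(%s && %s)", deparse_expr(e$lhs), deparse_expr(e$rhs)),
         or = sprintf("(%s || %s)", deparse_expr(e$lhs), deparse_expr(e$rhs)))
}

expr_names <- function(e) {
  if (e$type == "atom") e$name
  else unique(c(expr_names(e$lhs), expr_names(e$rhs)))
}

# Vectorized evaluation over a wide count matrix (one column per genome,
# absent genome = all-zero column).
eval_expr <- function(e, counts_of) {
  switch(e$type,
         atom = {
           x <- counts_of(e$name)
           switch(e$op,
                  "<" = x < e$value,
                  ">" = x > e$value,
                  "=" = x == e$value)
         },
         and = eval_expr(e$lhs, counts_of) & eval_expr(e$rhs, counts_of),
         or = eval_expr(e$lhs, counts_of) | eval_expr(e$rhs, counts_of))
}

#' Filter database k-mers by a boolean expression on genome counts
#'
#' A k-mer passes iff the expression evaluates true on its per-genome count
#' vector, with genomes in which it is absent contributing count 0; `=` is
#' exact integer equality.
#'
#' @param db A `kmer_db`.
#' @param expr A `filter_expr` from [parse_expr()], or its text.
#' @param out Optional path: write the passing records as a new database.
#' @return `data.table(kmer, gid, genome, count)` of records of passing
#'   k-mers (code order). When `out` is given, the new `kmer_db` handle is
#'   attached as attribute `"db"`.
#' @export
filter_database <- function(db, expr, out = NULL) {
  if (is.character(expr)) expr <- parse_expr(expr)
  unknown <- setdiff(expr_names(expr), db$genomes$names)
  if (length(unknown)) {
    abort(sprintf("expression references unknown genome(s): %s",
                  paste(unknown, collapse = ", ")), "mafkmer_lookup_error")
  }
  recs <- db_records(db)
  if (nrow(recs) == 0L) {
    res <- recs
  } else {
    wide <- data.table::dcast(recs, kmer ~ genome, value.var = "count",
                              fill = 0)
    zero <- numeric(nrow(wide))
    counts_of <- function(name) {
      if (name %in% names(wide)) wide[[name]] else zero
    }
    keep <- wide$kmer[eval_expr(expr, counts_of)]
    res <- recs[kmer %in% keep]
  }
  if (!is.null(out)) {
    ct <- count_table(db$k, db$genomes, db$alphabet,
                      counts = res[, list(kmer, gid, count)])
    attr(res, "db") <- write_count_table_db(ct, out)
  }
  res[]
}

## ---- queries ----------------------------------------------------------------

#' The G-quadruplex consensus as a regular expression
#'
#' Implements d(G3+ N1-7 G3+ N1-7 G3+ N1-7 G3+): four runs of three or more
#' guanines separated by 1--7 arbitrary bases.
#'
#' @return The pattern string.
#' @examples
#' grepl(g4_pattern(), "GGGAGGGAGGGAGGG")
#' @export
g4_pattern <- function() {
  "G{3,}[ACGT]{1,7}G{3,}[ACGT]{1,7}G{3,}[ACGT]{1,7}G{3,}"
}

#' Query k-mers from a database
#'
#' Exact queries (comma-separated list or one-per-line file) use the
#' byte-offset index via [lookup_kmer()]; regular-expression queries scan all
#' records and test the decoded k-mer string with substring-search semantics
#' (anchor with `^`/`$` for full-string matching). `g4 = TRUE` is shorthand
#' for `regex = g4_pattern()`.
#'
#' @param db A `kmer_db`.
#' @param kmers Character vector of k-mers, or one comma-separated string.
#' @param file Path to a file of k-mers, one per line.
#' @param regex A pattern (extended/PCRE regular expression).
#' @param g4 Use the G-quadruplex consensus pattern.
#' @return `data.table(kmer, gid, genome, count)` of matching records.
#' @export
query_kmers <- function(db, kmers = NULL, file = NULL, regex = NULL,
                        g4 = FALSE) {
  if (isTRUE(g4)) regex <- g4_pattern()
  n_modes <- sum(!is.null(kmers), !is.null(file), !is.null(regex))
  if (n_modes != 1L) {
    usage_error("supply exactly one of kmers, file, regex (or g4 = TRUE)")
  }
  empty <- data.table::data.table(kmer = character(0), gid = integer(0),
                                  genome = character(0), count = numeric(0))
  if (!is.null(regex)) {
    ok <- tryCatch({ grepl(regex, "A", perl = TRUE); TRUE },
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) abort(sprintf("invalid regular expression: '%s'", regex),
                   "mafkmer_pattern_error")
    recs <- db_records(db)
    return(recs[grepl(regex, kmer, perl = TRUE)][])
  }
  if (!is.null(file)) {
    if (!file.exists(file)) io_error(sprintf("query file '%s' not found", file))
    kmers <- readLines(file, warn = FALSE)
  }
  kmers <- toupper(trimws(unlist(strsplit(kmers, ",", fixed = TRUE))))
  kmers <- kmers[nzchar(kmers)]
  if (length(kmers) == 0L) return(empty)
  bad <- nchar(kmers) != db$k
  if (any(bad)) {
    usage_error(sprintf("query k-mer(s) of wrong length (expected %d): %s",
                        db$k, paste(kmers[bad], collapse = ", ")))
  }
  out <- lapply(kmers, function(km) {
    hit <- lookup_kmer(db, km)
    if (nrow(hit) == 0L) return(NULL)
    data.table::data.table(kmer = km,
                           gid = genome_id(db$genomes, hit$genome),
                           genome = hit$genome, count = hit$count)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) return(empty)
  data.table::rbindlist(out)
}
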