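# Classed conditions used across the package; the CLI maps these to exit codes.

abort <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "mafkmer_error", "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  ))
}

parse_error    <- function(msg) abort(msg, "mafkmer_parse_error")
capacity_error <- function(msg) abort(msg, "mafkmer_capacity_error")
usage_error    <- function(msg) abort(msg, "mafkmer_usage_error")
io_error       <- function(msg) abort(msg, "mafkmer_io_error")
format_error   <- function(msg) abort(msg, "mafkmer_format_error")

`%||%` <- function(a, b) if (is.null(a)) b else a
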