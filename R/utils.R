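# Internal helpers shared across modules.

# Locale-independent lexicographic sort (C collation via radix).
lex_sort <- function(x) sort(x, method = "radix")

lex_order <- function(...) order(..., method = "radix")

# Round half away from zero (half-up for positives), as printed arithmetic
# like (2 + 2 + 3)/3 = 2.33 expects; base round() is banker's rounding.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

popnet_error <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "popnet_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

abort_format <- function(msg, ...) popnet_error("popnet_format_error", msg, ...)
abort_value  <- function(msg, ...) popnet_error("popnet_value_error", msg, ...)
abort_lookup <- function(msg, ...) popnet_error("popnet_lookup_error", msg, ...)
abort_io     <- function(msg, ...) popnet_error("popnet_io_error", msg, ...)

# Evaluate an expression with the RNG seeded, restoring the caller's RNG
# state afterwards so library code never perturbs a user's stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

read_tsv_file <- function(path) {
  if (!file.exists(path)) {
    abort_io("file not found: %s", path)
  }
  utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    check.names = FALSE, colClasses = "character")
}

write_tsv_file <- function(df, path) {
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) abort_io("cannot write %s: %s", path, conditionMessage(ok))
  invisible(path)
}
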