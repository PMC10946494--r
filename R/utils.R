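# Internal helpers shared across modules.

# Round ppm values at the recording precision. base::round() implements IEEE
# round-half-to-even, which is the quantization convention used on ingest.
.roundPpm <- function(x, digits = 4L) round(x, digits = as.integer(digits))

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# seed = NA means "use the current RNG stream".
.withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) return(eval.parent(substitute(expr)))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Collapse a character vector for error messages.
.commas <- function(x, max = 10L) {
  x <- as.character(x)
  if (length(x) > max) x <- c(x[seq_len(max)], "...")
  paste(x, collapse = ", ")
}
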