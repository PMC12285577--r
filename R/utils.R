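#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

## Deterministic per-stage substream: keeps stage draws independent of the
## order in which stages are run while staying inside 32-bit integer range.
substream <- function(seed, k) {
  as.integer((as.numeric(seed) + 7919 * k) %% (.Machine$integer.max - 1L))
}

## Hash of an arbitrary R object via its canonical JSON serialization.
config_hash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(f))
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

is_prob <- function(x) is.numeric(x) && all(is.finite(x)) && all(x > 0) && all(x < 1)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == trunc(x)
}

stop_gx <- function(...) stop(sprintf(...), call. = FALSE)

## Format a proportion of printed counts the way cohort tables print them
## (one decimal, percentage). Used when recomputing composition shares.
pct <- function(num, denom, digits = 1) round(100 * num / denom, digits)
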