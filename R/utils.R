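`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## last-observation-carried-forward within one vector (no leading NA expected
## by callers, but tolerated: leading NAs stay NA)
locf <- function(x) {
  idx <- cumsum(!is.na(x))
  out <- c(NA, x[!is.na(x)])[idx + 1L]
  out
}

## split "a|b|c" cells into a list of character vectors; "" -> character(0)
split_codes <- function(x) {
  out <- strsplit(as.character(x), "|", fixed = TRUE)
  lapply(out, function(v) v[nzchar(v)])
}

join_codes <- function(lst) vapply(lst, paste, "", collapse = "|")

normalize_drug <- function(x) tolower(trimws(as.character(x)))

is_binary01 <- function(x) {
  is.logical(x) || (is.numeric(x) && all(x %in% c(0, 1)))
}

## deterministic sub-seed for a named sub-stream, kept below 2^31
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 104729L * as.integer(offset)) %% 2147483629L
}
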