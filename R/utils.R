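# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

ah_error <- function(message, class, ...) {
  cond <- structure(
    class = c(class, "assayharvest_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

is_blank <- function(x) is.na(x) | !nzchar(trimws(x))

#' Normalize cell text
#'
#' Collapses internal whitespace runs (including non-breaking spaces) to a
#' single space and trims; `NA` becomes the empty string. Applied to every
#' grid cell so downstream keyword matching is stable.
#'
#' @param x character vector of raw cell strings.
#' @return character vector of cleaned cells.
#' @keywords internal
normalize_cell <- function(x) {
  x[is.na(x)] <- ""
  x <- gsub("\u00a0", " ", x)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

# All numeric-looking tokens in a string, thousands separators stripped.
numeric_tokens <- function(text) {
  m <- gregexpr("[0-9][0-9,]*\\.?[0-9]*|\\.[0-9]+", text)
  tok <- regmatches(text, m)[[1]]
  if (!length(tok)) return(numeric(0))
  suppressWarnings(as.numeric(gsub(",", "", tok)))
}

# TRUE when the string carries at least one token with numeric value > 0.
# This is the title-row / data-row discriminator: drug-class title rows
# contain only strings, data rows always carry a positive concentration.
has_positive_number <- function(text) {
  v <- numeric_tokens(paste(text, collapse = " "))
  any(v > 0, na.rm = TRUE)
}

# Largest-remainder apportionment of n into integer counts ~ proportional to w.
apportion <- function(n, w) {
  raw <- n * w / sum(w)
  k <- floor(raw)
  rem <- n - sum(k)
  if (rem > 0) {
    extra <- order(raw - k, decreasing = TRUE)[seq_len(rem)]
    k[extra] <- k[extra] + 1L
  }
  as.integer(k)
}

utc_now <- function() format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

# Deterministic number-to-string formatting for CSV export (no scientific
# notation, no padding).
format_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) NA_character_
    else format(v, scientific = FALSE, trim = TRUE, drop0trailing = TRUE)
  }, character(1))
}
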