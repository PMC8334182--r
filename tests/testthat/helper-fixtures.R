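# Shared fixture builders; everything is constructed in code.

lex <- default_lexicon()

# A clean assay grid: header + one row per (drug, value) pair.
mk_grid <- function(drugs, values,
                    drug_header = "Antimicrobial drug",
                    sens_header = "Concentration (ppb)",
                    extra_headers = NULL, extra_cols = NULL) {
  header <- c(drug_header, sens_header, extra_headers)
  body <- cbind(drugs, as.character(values), extra_cols)
  unname(rbind(header, body))
}

mk_raw <- function(grid, doc_id = "doc", page = 1L, title = NA_character_) {
  raw_table(grid, doc_id = doc_id, page = page, page_title = title)
}

# Random clean table over the real drug vocabulary.
random_clean_grid <- function(n_rows = NULL) {
  n <- n_rows %||% sample(3:8, 1)
  drugs <- sample(names(lex$synonyms$drug$rows), n)
  mk_grid(drugs, sample(seq(5, 200, 5), n, replace = TRUE))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Write an HTML document with one table and body text.
write_html_fixture <- function(path, title, text, grid) {
  rows <- paste(vapply(seq_len(nrow(grid)), function(r)
    paste0("<tr>", paste0("<td>", grid[r, ], "</td>", collapse = ""),
           "</tr>"), character(1)), collapse = "\n")
  writeLines(paste0(
    "<html><head><meta charset=\"utf-8\"/><title>", title,
    "</title></head><body><p>", text, "</p><table>\n", rows,
    "\n</table></body></html>"), path, useBytes = TRUE)
  path
}

# Minimal master-sheet row.
mk_master_row <- function(drug, test = "Charm SL Beta-Lactam",
                          matrix = "Milk", type = "unknown",
                          low = 4, high = low, qualifier = "none",
                          source = "src") {
  tibble::tibble(drug = drug, test = test, matrix = matrix,
                 assay_type = type, sens_low_ppb = low,
                 sens_high_ppb = high, qualifier = qualifier,
                 animal = NA_character_, manufacturer = NA_character_,
                 mrl_ppb = NA_real_, tolerance_ppb = NA_real_,
                 source = source, last_updated = "t0")
}

# Incoming record in build_records() shape.
mk_incoming <- function(drug, test = "Charm SL Beta-Lactam",
                        matrix = "Milk", type = "unknown", low = 4,
                        high = low, qualifier = "none", source = "new",
                        year = 2020L, month = 6L) {
  tibble::tibble(drug = drug, test = test, matrix = matrix,
                 assay_type = type, animal = NA_character_,
                 manufacturer = NA_character_, sens_kind = "point",
                 sens_low_ppb = low, sens_high_ppb = high,
                 qualifier = qualifier, original_unit = "ppb",
                 mrl_ppb = NA_real_, tolerance_ppb = NA_real_,
                 source = source, doc_id = "d", page = 1L,
                 doc_year = year, doc_month = month)
}

# Character-scan whole-word oracle, independent of the regex engine:
# an occurrence counts iff the characters just before and after are
# absent or non-word.
oracle_word_hit <- function(text, keyword) {
  t <- tolower(text); k <- tolower(keyword)
  if (!nzchar(k)) return(FALSE)
  start <- 1
  is_word <- function(ch) grepl("^[a-z0-9_]$", ch)
  repeat {
    i <- regexpr(k, substr(t, start, nchar(t)), fixed = TRUE)
    if (i == -1L) return(FALSE)
    pos <- start + i - 1L
    before <- if (pos > 1) substr(t, pos - 1, pos - 1) else ""
    after_pos <- pos + nchar(k)
    after <- if (after_pos <= nchar(t)) substr(t, after_pos, after_pos)
             else ""
    if ((before == "" || !is_word(before)) &&
        (after == "" || !is_word(after))) return(TRUE)
    start <- pos + 1L
  }
}

# Literal keyword surfaces of a '\W...\W' pattern: '.?' (any single
# optional character) realized both as absent and as a concrete character
# (a space inside the keyword, an 's' at its end).
keyword_surfaces <- function(pattern) {
  alts <- strsplit(pattern, "|", fixed = TRUE)[[1]]
  alts <- gsub("\\\\W", "", alts)
  unique(unlist(lapply(alts, function(a) {
    realized <- sub("\\.\\?$", "s", a)
    realized <- gsub(".?", " ", realized, fixed = TRUE)
    c(gsub(".?", "", a, fixed = TRUE), realized)
  })))
}
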