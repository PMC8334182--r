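# The lexicon: keyword ensembles, the field-alias dictionary, entity synonym
# tables, boundary-safe matching, method-name splitting, and PMI synonym
# candidate scoring.

# ---- pattern compilation -----------------------------------------------

#' Compile a whole-word keyword pattern to a boundary-safe regex
#'
#' Dictionary patterns follow the `\W...\W` convention: the keyword must not
#' be preceded or followed by a word character, so "urine" never fires inside
#' "purines" nor "tissue" inside "intertissued". A literal `\W` cannot match
#' at the start or end of a string, which would wrongly reject a cell that
#' *is* the keyword; each `\W` edge is therefore compiled to a lookaround
#' (`(?<!\w)` / `(?!\w)`) that treats string edges as boundaries. A `|` inside
#' a pattern separates alternatives, each carrying its own edges, and `.?`
#' stands for any single optional character. Everything else is literal.
#'
#' @param pattern a pattern string such as `"\\Wserum\\W|\\WSera\\W"`.
#' @return a PCRE string (use with `perl = TRUE`, case-insensitive).
#' @export
#' @examples
#' grepl(compile_keyword("\\Wurine\\W"), "Urine samples",
#'       perl = TRUE, ignore.case = TRUE)
#' grepl(compile_keyword("\\Wurine\\W"), "purines",
#'       perl = TRUE, ignore.case = TRUE)
compile_keyword <- function(pattern) {
  alts <- strsplit(pattern, "|", fixed = TRUE)[[1]]
  alts <- vapply(alts, function(a) {
    lead <- grepl("^\\\\W", a)
    trail <- grepl("\\\\W$", a)
    body <- sub("^\\\\W", "", a)
    body <- sub("\\\\W$", "", body)
    # escape regex metacharacters, then restore the '.?' wildcard
    body <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", body)
    body <- gsub("\\.\\?", ".?", body, fixed = TRUE)
    paste0(if (lead) "(?<!\\w)", body, if (trail) "(?!\\w)")
  }, character(1), USE.NAMES = FALSE)
  paste(alts, collapse = "|")
}

# Boundary-safe pattern for a literal entity name (synonym-table variants).
entity_pattern <- function(name) {
  paste0("(?<!\\w)", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", name), "(?!\\w)")
}

validate_pattern <- function(pattern) {
  compiled <- compile_keyword(pattern)
  ok <- tryCatch(
    { regexpr(compiled, "", perl = TRUE); TRUE },
    error = function(e) FALSE
  )
  if (!ok) {
    ah_error(sprintf("malformed keyword pattern: %s", pattern),
             "assayharvest_config_error")
  }
  compiled
}

# ---- constructors -------------------------------------------------------

#' Keyword ensemble
#'
#' An ordered list of whole-word patterns scanned for one parameter type
#' (`matrix`, `desired_field` or `unit`). Patterns are compiled and validated
#' at construction; a malformed pattern is a configuration error raised here,
#' never at match time.
#'
#' @param parameter_type one of `"matrix"`, `"desired_field"`, `"unit"`.
#' @param patterns character vector of `\W...\W` patterns.
#' @return a `keyword_ensemble` object.
#' @export
keyword_ensemble <- function(parameter_type, patterns) {
  parameter_type <- match.arg(parameter_type,
                              c("matrix", "desired_field", "unit"))
  if (!length(patterns)) {
    ah_error("keyword ensemble needs at least one pattern",
             "assayharvest_config_error")
  }
  compiled <- vapply(patterns, validate_pattern, character(1),
                     USE.NAMES = FALSE)
  structure(list(parameter_type = parameter_type,
                 patterns = patterns, compiled = compiled),
            class = "keyword_ensemble")
}

#' Field-alias dictionary
#'
#' Maps canonical field names (Drug, Sensitivity, Test, Matrix, MRL,
#' Tolerance, plus Type/Animal/Manufacturer/Unit) to the header spellings
#' found in source documents. An alias string listed under two canonical
#' names is rejected at construction.
#'
#' @param entries named list: canonical name -> character vector of alias
#'   patterns (whole-word convention).
#' @return a `field_dictionary` object.
#' @export
field_dictionary <- function(entries) {
  if (anyDuplicated(names(entries))) {
    ah_error("duplicate canonical field names", "assayharvest_config_error")
  }
  all_aliases <- tolower(unlist(entries, use.names = FALSE))
  if (anyDuplicated(all_aliases)) {
    dup <- all_aliases[duplicated(all_aliases)][1]
    ah_error(sprintf("alias '%s' mapped to two canonical fields", dup),
             "assayharvest_config_error")
  }
  compiled <- lapply(entries, function(p)
    vapply(p, validate_pattern, character(1), USE.NAMES = FALSE))
  structure(list(entries = entries, compiled = compiled),
            class = "field_dictionary")
}

#' Entity synonym table
#'
#' One row per canonical entity (the most frequently used name); the
#' remaining columns hold variant spellings. The canonical name is always
#' matchable as its own variant. A variant may appear in at most one row.
#'
#' @param entity_class `"drug"`, `"test"`, `"matrix"`, `"manufacturer"` or
#'   `"animal"`.
#' @param rows named list: canonical name -> character vector of variants
#'   (the canonical itself need not be listed; it is added).
#' @return a `synonym_table` object.
#' @export
synonym_table <- function(entity_class, rows) {
  entity_class <- match.arg(entity_class,
                            c("drug", "test", "matrix", "manufacturer",
                              "animal"))
  rows <- lapply(seq_along(rows), function(i) {
    canonical <- names(rows)[i]
    unique(c(canonical, rows[[i]]))
  })
  names(rows) <- vapply(rows, `[`, character(1), 1)
  folded <- tolower(unlist(rows, use.names = FALSE))
  if (anyDuplicated(folded)) {
    dup <- folded[duplicated(folded)][1]
    ah_error(sprintf("variant '%s' appears in two synonym rows (%s)",
                     dup, entity_class),
             "assayharvest_config_error")
  }
  structure(list(entity_class = entity_class, rows = rows),
            class = "synonym_table")
}

#' @export
print.synonym_table <- function(x, ...) {
  cat(sprintf("<synonym_table: %s, %d canonical names, %d variants>\n",
              x$entity_class, length(x$rows),
              length(unlist(x$rows))))
  invisible(x)
}

# ---- dictionary file readers -------------------------------------------

#' Read a synonym table from CSV
#'
#' File layout: first column the canonical (most frequent) name, remaining
#' columns variant spellings, one name per column; rows may be ragged.
#'
#' @param path CSV file path.
#' @param entity_class passed to [synonym_table()].
#' @return a `synonym_table`.
#' @export
read_synonym_table <- function(path, entity_class) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  rows <- lapply(lines, function(l) {
    cells <- scan(text = l, what = character(), sep = ",", quote = "\"",
                  quiet = TRUE, strip.white = TRUE)
    cells[nzchar(cells)]
  })
  names(rows) <- vapply(rows, `[`, character(1), 1)
  rows <- lapply(rows, function(r) r[-1])
  synonym_table(entity_class, rows)
}

read_yaml_dict <- function(path) {
  # minimal YAML subset reader: "key:" lines followed by "  - 'value'" items
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  out <- list(); key <- NULL
  for (l in lines) {
    if (grepl("^[^ ].*:\\s*$", l)) {
      key <- sub(":\\s*$", "", l)
      out[[key]] <- character(0)
    } else if (grepl("^\\s*-\\s*", l)) {
      v <- sub("^\\s*-\\s*", "", l)
      v <- sub("^'", "", sub("'\\s*$", "", v))
      out[[key]] <- c(out[[key]], v)
    }
  }
  out
}

#' Assemble the default lexicon
#'
#' Loads the keyword ensembles, field-alias dictionary and entity synonym
#' tables shipped with the package (the controlled vocabularies of
#' commercial rapid residue assays: ~90 test names, 56 drugs, 5 matrices,
#' 7 manufacturers, 10 animals). Every component can be overridden by
#' passing a replacement.
#'
#' @param ensembles named list of [keyword_ensemble()]s
#'   (`matrix`, `desired_field`, `unit`).
#' @param fields a [field_dictionary()].
#' @param synonyms named list of [synonym_table()]s
#'   (`drug`, `test`, `matrix`, `manufacturer`, `animal`).
#' @return an `ah_lexicon` object.
#' @export
#' @examples
#' lex <- default_lexicon()
#' match_keyword("Urine samples", lex$ensembles$matrix)
default_lexicon <- function(ensembles = NULL, fields = NULL,
                            synonyms = NULL) {
  ext <- function(f) system.file("extdata", f, package = "assayharvest",
                                 mustWork = TRUE)
  if (is.null(ensembles)) {
    raw <- read_yaml_dict(ext("keyword_ensembles.yml"))
    ensembles <- lapply(names(raw), function(k) keyword_ensemble(k, raw[[k]]))
    names(ensembles) <- names(raw)
  }
  if (is.null(fields)) {
    fields <- field_dictionary(read_yaml_dict(ext("field_aliases.yml")))
  }
  if (is.null(synonyms)) {
    synonyms <- list(
      drug = read_synonym_table(ext("drug_synonyms.csv"), "drug"),
      test = read_synonym_table(ext("test_synonyms.csv"), "test"),
      matrix = read_synonym_table(ext("matrix_synonyms.csv"), "matrix"),
      manufacturer = read_synonym_table(ext("manufacturer_synonyms.csv"),
                                        "manufacturer"),
      animal = read_synonym_table(ext("animal_synonyms.csv"), "animal")
    )
  }
  structure(list(ensembles = ensembles, fields = fields,
                 synonyms = synonyms,
                 assay_types = c("sequential", "competitive", "quantitative")),
            class = "ah_lexicon")
}

#' @export
print.ah_lexicon <- function(x, ...) {
  cat("<assayharvest lexicon>\n")
  cat("  ensembles:", paste(names(x$ensembles), collapse = ", "), "\n")
  cat("  fields:", paste(names(x$fields$entries), collapse = ", "), "\n")
  for (s in names(x$synonyms)) {
    cat(sprintf("  synonyms$%s: %d canonical names\n", s,
                length(x$synonyms[[s]]$rows)))
  }
  invisible(x)
}

# ---- matching -----------------------------------------------------------

#' Match a keyword ensemble against text
#'
#' Whole-word, case-insensitive matching: a keyword fires only when not
#' immediately preceded or followed by a word character (string start/end
#' count as boundaries). Spans are reported in reading order.
#'
#' @param text a normalized cell or body-text string.
#' @param ensemble a [keyword_ensemble()].
#' @return data frame with columns `pattern`, `match`, `start`, `end`;
#'   zero rows when nothing matches.
#' @export
match_keyword <- function(text, ensemble) {
  stopifnot(inherits(ensemble, "keyword_ensemble"))
  out <- list()
  for (i in seq_along(ensemble$compiled)) {
    m <- gregexpr(ensemble$compiled[i], text, perl = TRUE,
                  ignore.case = TRUE)[[1]]
    if (m[1] == -1L) next
    out[[length(out) + 1L]] <- data.frame(
      pattern = ensemble$patterns[i],
      match = regmatches(text, list(m))[[1]],
      start = as.integer(m),
      end = as.integer(m) + attr(m, "match.length") - 1L,
      stringsAsFactors = FALSE
    )
  }
  if (!length(out)) {
    return(data.frame(pattern = character(0), match = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$end), , drop = FALSE]
}

#' Canonicalize a header cell to a field name
#'
#' Tests the raw header against every alias pattern. When aliases of two
#' *different* canonical fields match, the longer matched span wins (a more
#' specific alias such as "Test Sensitivity" beats the generic "Test");
#' an exact span tie across canonicals is an ambiguity error, which marks a
#' dictionary bug.
#'
#' @param raw_header one header cell string.
#' @param dict a [field_dictionary()].
#' @return the canonical field name, or `NA_character_` when nothing matches.
#' @export
#' @examples
#' canonicalize_field("Antimicrobial drug", default_lexicon()$fields)
canonicalize_field <- function(raw_header, dict) {
  stopifnot(inherits(dict, "field_dictionary"))
  if (is_blank(raw_header)) return(NA_character_)
  best <- character(0); best_len <- -1L
  for (canonical in names(dict$compiled)) {
    for (pat in dict$compiled[[canonical]]) {
      m <- regexpr(pat, raw_header, perl = TRUE, ignore.case = TRUE)
      if (m[1] == -1L) next
      len <- attr(m, "match.length")
      if (len > best_len) { best <- canonical; best_len <- len }
      else if (len == best_len && !canonical %in% best) {
        best <- c(best, canonical)
      }
    }
  }
  if (!length(best)) return(NA_character_)
  if (length(best) > 1) {
    ah_error(sprintf("header '%s' matches aliases of several fields: %s",
                     raw_header, paste(best, collapse = ", ")),
             "assayharvest_ambiguity_error")
  }
  best
}

#' Canonicalize an entity name via a synonym table
#'
#' An exact case-insensitive match against any variant wins; otherwise the
#' longest variant contained in the input wins (so a page title
#' "Charm Kidney Inhibition Swab Test" resolves to "Charm KIS"). Ties break
#' by table row order. Idempotent: a canonical name maps to itself.
#'
#' @param raw_name entity name, already stripped of method suffixes.
#' @param table a [synonym_table()].
#' @return list with `canonical` and `variant`, or `NULL` when no variant
#'   matches.
#' @export
canonicalize_entity <- function(raw_name, table) {
  stopifnot(inherits(table, "synonym_table"))
  raw <- trimws(raw_name)
  if (!nzchar(raw)) return(NULL)
  folded <- tolower(raw)
  for (canonical in names(table$rows)) {
    hit <- table$rows[[canonical]][tolower(table$rows[[canonical]]) == folded]
    if (length(hit)) return(list(canonical = canonical, variant = hit[1]))
  }
  best <- NULL; best_len <- 0L
  for (canonical in names(table$rows)) {
    for (v in table$rows[[canonical]]) {
      if (nchar(v) > best_len &&
          grepl(tolower(v), folded, fixed = TRUE)) {
        best <- list(canonical = canonical, variant = v)
        best_len <- nchar(v)
      }
    }
  }
  best
}

#' Locate entity mentions in free text
#'
#' Boundary-safe, case-insensitive scan of every variant of every synonym
#' row through a body-text string; used to pick a test name out of document
#' text and to spot drugs mentioned in text but missing from a table.
#'
#' @param text document text.
#' @param table a [synonym_table()].
#' @return data frame `canonical`, `variant`, `start`, `end` in reading
#'   order; overlapping mentions are all reported.
#' @export
find_entities <- function(text, table) {
  stopifnot(inherits(table, "synonym_table"))
  out <- list()
  if (!nzchar(text)) {
    return(data.frame(canonical = character(0), variant = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE))
  }
  for (canonical in names(table$rows)) {
    for (v in table$rows[[canonical]]) {
      m <- gregexpr(entity_pattern(v), text, perl = TRUE,
                    ignore.case = TRUE)[[1]]
      if (m[1] == -1L) next
      out[[length(out) + 1L]] <- data.frame(
        canonical = canonical, variant = v,
        start = as.integer(m),
        end = as.integer(m) + attr(m, "match.length") - 1L,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(canonical = character(0), variant = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$start, -res$end), , drop = FALSE]
}

#' Split an assay method off a drug or test field
#'
#' Source sheets often carry the assay chemistry (sequential, competitive,
#' quantitative) in the same field as the drug or test name, comma-separated
#' before or after it. The method token is removed and returned separately.
#'
#' @param raw_field the raw cell, e.g. `"Penicillin, sequential"`.
#' @return list with `name` (remainder, trimmed) and `method`
#'   (lower-case method word or `NA_character_`).
#' @export
#' @examples
#' split_method("Penicillin, sequential")
#' split_method("quantitative, Gentamicin")
split_method <- function(raw_field) {
  stopifnot(nzchar(raw_field))
  methods <- "(sequential|competitive|quantitative)"
  s <- trimws(raw_field)
  only_re <- sprintf("^%s$", methods)
  if (grepl(only_re, s, ignore.case = TRUE)) {
    return(list(name = "", method = tolower(s)))
  }
  trail_re <- sprintf(",\\s*%s\\s*$", methods)
  lead_re <- sprintf("^%s\\s*,\\s*", methods)
  m <- regexpr(trail_re, s, ignore.case = TRUE, perl = TRUE)
  if (m[1] != -1L) {
    method <- tolower(gsub("[,\\s]", "", regmatches(s, m), perl = TRUE))
    return(list(name = trimws(sub(trail_re, "", s, ignore.case = TRUE)),
                method = method))
  }
  m <- regexpr(lead_re, s, ignore.case = TRUE, perl = TRUE)
  if (m[1] != -1L) {
    method <- tolower(gsub("[,\\s]", "", regmatches(s, m), perl = TRUE))
    return(list(name = trimws(sub(lead_re, "", s, ignore.case = TRUE)),
                method = method))
  }
  list(name = s, method = NA_character_)
}

# ---- PMI synonym-candidate scoring -------------------------------------

#' Score word pairs by pointwise mutual information
#'
#' Document-level co-occurrence statistics in the PMI-IR style: for words a
#' and b, `pmi = log2(count_ab * n_docs / (count_a * count_b))` with counts
#' of documents containing the word(s). High-PMI pairs are synonym
#' *candidates* for human review; nothing is auto-merged.
#'
#' @param corpus list of documents, each a character vector of tokens
#'   (tokens are case-folded; within-document duplicates ignored).
#' @return data frame `word_a`, `word_b`, `count_a`, `count_b`, `count_ab`,
#'   `n_docs`, `pmi` (bits), for every unordered pair co-occurring in at
#'   least one document; sorted by `pmi` descending, ties by `count_ab`
#'   descending then lexicographically.
#' @export
#' @examples
#' docs <- rep(list(c("charm", "kis")), 2)
#' pmi_score(c(docs, rep(list("other"), 6)))
pmi_score <- function(corpus) {
  if (!length(corpus)) {
    ah_error("empty corpus", "assayharvest_config_error")
  }
  docs <- lapply(corpus, function(d) sort(unique(tolower(d))))
  n <- length(docs)
  word_count <- table(unlist(docs))
  pair_env <- new.env(hash = TRUE, parent = emptyenv())
  for (d in docs) {
    if (length(d) < 2) next
    idx <- utils::combn(length(d), 2)
    keys <- paste(d[idx[1, ]], d[idx[2, ]], sep = "\x1f")
    for (k in keys) {
      assign(k, (if (exists(k, pair_env)) get(k, pair_env) else 0L) + 1L,
             pair_env)
    }
  }
  keys <- ls(pair_env)
  if (!length(keys)) {
    return(data.frame(word_a = character(0), word_b = character(0),
                      count_a = integer(0), count_b = integer(0),
                      count_ab = integer(0), n_docs = integer(0),
                      pmi = numeric(0), stringsAsFactors = FALSE))
  }
  ab <- vapply(keys, get, integer(1), envir = pair_env)
  words <- do.call(rbind, strsplit(keys, "\x1f", fixed = TRUE))
  ca <- as.integer(word_count[words[, 1]])
  cb <- as.integer(word_count[words[, 2]])
  res <- data.frame(word_a = words[, 1], word_b = words[, 2],
                    count_a = ca, count_b = cb, count_ab = as.integer(ab),
                    n_docs = n,
                    pmi = log2(ab * n / (ca * cb)),
                    stringsAsFactors = FALSE)
  res <- res[order(-res$pmi, -res$count_ab, res$word_a, res$word_b), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}
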