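# Turning stored documents into RawTable grids plus document-level context,
# behind a pluggable extractor contract.

#' Construct a raw table
#'
#' The unit of all repair operations: a rectangular grid of plain-text cell
#' strings with provenance. Ragged input rows are padded with empty strings;
#' every cell is whitespace-normalized.
#'
#' @param grid character matrix, or list of character vectors (rows).
#' @param doc_id document identifier.
#' @param page 1-based page number (HTML documents: 1).
#' @param page_title document/page title, or `NA`.
#' @param source_locator where the document came from.
#' @return a `raw_table` object.
#' @export
raw_table <- function(grid, doc_id = "", page = 1L, page_title = NA_character_,
                      source_locator = "") {
  if (is.list(grid)) {
    width <- max(vapply(grid, length, integer(1)))
    grid <- do.call(rbind, lapply(grid, function(r) {
      r <- as.character(r)
      c(r, rep("", width - length(r)))
    }))
  }
  if (!is.matrix(grid)) grid <- matrix(as.character(grid), nrow = 1)
  if (nrow(grid) < 1 || ncol(grid) < 1) {
    ah_error("a raw table needs at least one row and one column",
             "assayharvest_extraction_error")
  }
  grid[] <- normalize_cell(grid)
  structure(list(grid = grid, doc_id = doc_id, page = as.integer(page),
                 page_title = page_title, source_locator = source_locator),
            class = "raw_table")
}

#' @export
print.raw_table <- function(x, ...) {
  cat(sprintf("<raw_table %dx%d doc=%s page=%d>\n", nrow(x$grid),
              ncol(x$grid), x$doc_id, x$page))
  invisible(x)
}

#' Extract tables from an HTML document
#'
#' Returns one `raw_table` per leaf `<table>` element (nested tables are
#' flattened to their innermost tables) in document order; the page title
#' comes from the `<title>` element. Layout-only tables are returned too --
#' relevance filtering happens downstream.
#'
#' @param path HTML file.
#' @param doc_id,source_locator provenance; default to the path.
#' @return list of [raw_table()]s (empty when the page has no tables).
#' @export
extract_tables_html <- function(path, doc_id = basename(path),
                                source_locator = path) {
  doc <- tryCatch(xml2::read_html(path),
                  error = function(e)
                    ah_error(sprintf("cannot parse HTML %s: %s", path,
                                     conditionMessage(e)),
                             "assayharvest_extraction_error"))
  title_node <- xml2::xml_find_first(doc, "//title")
  title <- if (inherits(title_node, "xml_missing")) NA_character_
           else normalize_cell(xml2::xml_text(title_node))
  tables <- xml2::xml_find_all(doc, "//table[not(.//table)]")
  out <- list()
  for (tbl in tables) {
    trs <- xml2::xml_find_all(tbl, ".//tr")
    rows <- lapply(trs, function(tr) {
      cells <- xml2::xml_find_all(tr, "./td|./th")
      vapply(cells, function(c) xml2::xml_text(c), character(1))
    })
    rows <- rows[vapply(rows, length, integer(1)) > 0]
    if (!length(rows)) next
    out[[length(out) + 1L]] <- raw_table(rows, doc_id = doc_id, page = 1L,
                                         page_title = title,
                                         source_locator = source_locator)
  }
  out
}

#' Full text of an HTML document
#'
#' @param path HTML file.
#' @return list with `text` (whitespace-normalized body text) and `title`.
#' @export
html_document_text <- function(path) {
  doc <- xml2::read_html(path)
  title_node <- xml2::xml_find_first(doc, "//title")
  list(text = normalize_cell(xml2::xml_text(doc)),
       title = if (inherits(title_node, "xml_missing")) NA_character_
               else normalize_cell(xml2::xml_text(title_node)))
}

#' The JSON page-grid extractor
#'
#' A `GridExtractor` is any function taking a document path and returning
#' `list(title = <string or NA>, pages = list(list(text = <string>,
#' grids = list(<character matrix>))))`. This decouples table-region
#' detection (a black box with many interchangeable engines) from the
#' repair pipeline, and lets tests inject grids directly.
#'
#' `json_grid_extractor` reads the package's plain-text page-grid document
#' format: a JSON object `{"title": ..., "pages": [{"text": ...,
#' "tables": [[[cell, ...], ...], ...]}]}`, which is also what the
#' synthetic-corpus generator emits for its PDF-kind documents.
#'
#' @param path document path.
#' @return the standardized page list described above.
#' @export
json_grid_extractor <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    ah_error(sprintf("cannot parse page-grid document %s: %s",
                                     path, conditionMessage(e)),
                             "assayharvest_extraction_error"))
  pages <- lapply(obj$pages, function(p) {
    grids <- lapply(p$tables, function(tab) {
      rows <- lapply(tab, function(r) vapply(r, function(x)
        if (is.null(x)) "" else as.character(x), character(1)))
      width <- max(vapply(rows, length, integer(1)))
      do.call(rbind, lapply(rows, function(r)
        c(r, rep("", width - length(r)))))
    })
    list(text = if (is.null(p$text)) "" else as.character(p$text),
         grids = grids)
  })
  list(title = if (is.null(obj$title)) NA_character_
               else as.character(obj$title),
       pages = pages)
}

#' Extract tables from a PDF-kind document
#'
#' Walks the document page by page through a `GridExtractor` (see
#' [json_grid_extractor()]) and emits each candidate grid as a
#' [raw_table()], normalized to rectangular cells, with the page recorded.
#' Pages without tables contribute nothing.
#'
#' @param path stored document path.
#' @param extractor a GridExtractor function.
#' @param doc_id,source_locator provenance.
#' @return list of [raw_table()]s.
#' @export
extract_tables_pdf <- function(path, extractor = json_grid_extractor,
                               doc_id = basename(path),
                               source_locator = path) {
  parsed <- extractor(path)
  out <- list()
  for (i in seq_along(parsed$pages)) {
    for (g in parsed$pages[[i]]$grids) {
      out[[length(out) + 1L]] <- raw_table(g, doc_id = doc_id, page = i,
                                           page_title = parsed$title,
                                           source_locator = source_locator)
    }
  }
  out
}

#' Read a stored document (tables + text + title)
#'
#' Dispatches on the document kind and returns everything downstream stages
#' need in one pass.
#'
#' @param ref a manifest row (needs `stored_path` or `source_locator`,
#'   `kind`, `doc_id`).
#' @param extractor GridExtractor for PDF-kind documents.
#' @return list with `tables` (list of [raw_table()]), `text`, `title`.
#' @export
read_document <- function(ref, extractor = json_grid_extractor) {
  ref <- as.list(ref)
  path <- ref$stored_path %||% ref$source_locator
  if (identical(ref$kind, "html")) {
    txt <- html_document_text(path)
    list(tables = extract_tables_html(path, doc_id = ref$doc_id,
                                      source_locator = ref$source_locator),
         text = txt$text, title = txt$title)
  } else {
    parsed <- extractor(path)
    list(tables = extract_tables_pdf(path, extractor, doc_id = ref$doc_id,
                                     source_locator = ref$source_locator),
         text = paste(vapply(parsed$pages, function(p) p$text, character(1)),
                      collapse = "\n"),
         title = parsed$title)
  }
}

#' Infer document-level context fields
#'
#' Fields that live outside the table itself: the matrix (first matrix
#' keyword in the body text, else in the URL path segments), the test name
#' (the page title when present, else the first known test name mentioned
#' in the text) and the assay type (first of sequential / competitive /
#' quantitative, whole-word, case-folded). Each present field records its
#' provenance; an all-absent result is valid.
#'
#' @param document_text full extracted text (may be empty).
#' @param lexicon an [default_lexicon()] object.
#' @param page_title document title or `NA`.
#' @param url source locator; path segments are split on "/", "-", "_".
#' @return list with `matrix`, `test`, `assay_type` (each a string or `NA`)
#'   and `provenance` (named character vector).
#' @export
#' @examples
#' lex <- default_lexicon()
#' extract_context("Detects residues in milk at or below tolerance.", lex)
extract_context <- function(document_text, lexicon,
                            page_title = NA_character_, url = "") {
  stopifnot(inherits(lexicon, "ah_lexicon"))
  prov <- c(matrix = NA_character_, test = NA_character_,
            assay_type = NA_character_)
  canon_matrix <- function(raw) {
    hit <- canonicalize_entity(raw, lexicon$synonyms$matrix)
    if (is.null(hit)) raw else hit$canonical
  }

  mat <- NA_character_
  mk <- match_keyword(document_text, lexicon$ensembles$matrix)
  if (nrow(mk)) {
    mat <- canon_matrix(mk$match[1])
    prov["matrix"] <- "body_text"
    if (length(unique(mk$match)) > 1) {
      message(sprintf("multiple matrix mentions (%s); taking first",
                      paste(unique(tolower(mk$match)), collapse = ", ")))
    }
  } else if (nzchar(url)) {
    segs <- strsplit(url, "[/_-]+")[[1]]
    for (s in segs) {
      if (nrow(match_keyword(s, lexicon$ensembles$matrix))) {
        mat <- canon_matrix(s)
        prov["matrix"] <- "url"
        break
      }
    }
  }

  test <- NA_character_
  if (!is.na(page_title) && nzchar(page_title)) {
    test <- page_title
    prov["test"] <- "page_title"
  } else {
    hits <- find_entities(document_text, lexicon$synonyms$test)
    if (nrow(hits)) {
      test <- hits$canonical[1]
      prov["test"] <- "body_text"
    }
  }

  type <- NA_character_
  m <- regexpr("(?<!\\w)(sequential|competitive|quantitative)(?!\\w)",
               document_text, perl = TRUE, ignore.case = TRUE)
  if (m[1] != -1L) {
    type <- tolower(regmatches(document_text, m))
    prov["assay_type"] <- "body_text"
  }

  list(matrix = mat, test = test, assay_type = type, provenance = prov)
}

#' Serialize raw tables as JSON lines
#'
#' Pipeline checkpoint format: one JSON object per line with doc_id, page,
#' page_title and the grid.
#'
#' @param tables list of [raw_table()]s.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tables_jsonl <- function(tables, path) {
  lines <- vapply(tables, function(t) {
    jsonlite::toJSON(list(doc_id = t$doc_id, page = t$page,
                          page_title = t$page_title,
                          grid = apply(t$grid, 1, as.list, simplify = FALSE)),
                     auto_unbox = TRUE, na = "null")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
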