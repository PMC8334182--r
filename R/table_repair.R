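# Classifying tables as relevant and repairing the structural pathologies
# that PDF/HTML extraction leaves behind: banner headlines above the header,
# drug-class title rows inside the body, side-by-side repeated column
# groups, and silently dropped final rows.

#' Is a raw table a relevant assay table?
#'
#' True iff at least one cell matches a desired-field keyword (the
#' sensitivity / concentration / detection family) AND at least one cell
#' matches a Drug header alias or a known drug name. Page-layout tables
#' (navigation links and the like) fail both tests.
#'
#' @param table a [raw_table()].
#' @param lexicon an [default_lexicon()].
#' @return logical scalar.
#' @export
is_relevant <- function(table, lexicon) {
  stopifnot(inherits(table, "raw_table"), inherits(lexicon, "ah_lexicon"))
  cells <- as.vector(table$grid)
  cells <- cells[nzchar(cells)]
  if (!length(cells)) return(FALSE)
  blob <- paste(cells, collapse = "\n")
  if (!nrow(match_keyword(blob, lexicon$ensembles$desired_field))) {
    return(FALSE)
  }
  drug_aliases <- lexicon$fields$compiled[["Drug"]]
  for (pat in drug_aliases) {
    if (grepl(pat, blob, perl = TRUE, ignore.case = TRUE)) return(TRUE)
  }
  nrow(find_entities(blob, lexicon$synonyms$drug)) > 0
}

#' Identify the header row and the column-to-field map
#'
#' The header is the first row maximizing the number of cells that
#' canonicalize to a field name (ties go to the earliest row). Each column
#' is mapped to its canonical field, `NA` when its header cell matches no
#' alias.
#'
#' @param table a [raw_table()].
#' @param fields a [field_dictionary()].
#' @return list with `index` (header row) and `map` (character vector,
#'   canonical name or `NA` per column).
#' @export
identify_header <- function(table, fields) {
  grid <- table$grid
  maps <- vector("list", nrow(grid))
  scores <- integer(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    maps[[r]] <- vapply(grid[r, ], canonicalize_field, character(1),
                        dict = fields, USE.NAMES = FALSE)
    scores[r] <- sum(!is.na(maps[[r]]))
  }
  if (max(scores) == 0L) {
    ah_error(sprintf("no header row found (doc %s page %d)",
                     table$doc_id, table$page),
             "assayharvest_header_error",
             doc_id = table$doc_id, page = table$page)
  }
  idx <- which(scores == max(scores))[1]
  list(index = idx, map = maps[[idx]])
}

#' Remove banner and drug-class title rows
#'
#' Rows *above* the header (banner headlines) are removed and flagged
#' `had_banner`. Among body rows (below the header), any row whose cells
#' contain no token with a positive real value is a drug-class title row --
#' data rows always carry a positive concentration -- and is removed and
#' flagged `had_title_rows`. The header itself (also number-free) is never
#' touched, and no row containing a positive number is ever removed.
#'
#' @param grid character matrix (full table, header included).
#' @param header_index header row position in `grid`.
#' @return list with `body` (cleaned body matrix), `flags`, and `log`
#'   (list of removal actions with row content).
#' @export
drop_title_rows <- function(grid, header_index) {
  flags <- character(0)
  log <- list()
  if (header_index > 1) {
    for (r in seq_len(header_index - 1)) {
      log[[length(log) + 1L]] <- list(action = "remove_banner", row = r,
                                      cells = unname(grid[r, ]))
    }
    flags <- c(flags, "had_banner")
  }
  body <- grid[seq_len(nrow(grid)) > header_index, , drop = FALSE]
  if (nrow(body)) {
    keep <- apply(body, 1, has_positive_number)
    if (any(!keep)) {
      for (r in which(!keep)) {
        log[[length(log) + 1L]] <- list(action = "remove_title_row",
                                        row = header_index + r,
                                        cells = unname(body[r, ]))
      }
      flags <- c(flags, "had_title_rows")
      body <- body[keep, , drop = FALSE]
    }
  }
  list(body = body, flags = flags, log = log)
}

#' Merge side-by-side repeated column groups
#'
#' When the canonical header sequence is a block repeated k >= 2 times
#' (e.g. Drug, Sensitivity, Drug, Sensitivity), the table was split into
#' sub-tables placed side by side; the blocks are stacked vertically in
#' left-to-right order and rows left entirely empty by the stacking are
#' dropped. Block detection requires exact canonical-sequence equality;
#' anything looser risks corrupting genuinely distinct columns. With no
#' repeat the input is returned unchanged.
#'
#' @param body body matrix (no header row).
#' @param header_map canonical field per column (from [identify_header()]).
#' @param raw_header original header cells (optional, stacked in parallel).
#' @return list with `body`, `header_map`, `raw_header`, `merged` (logical)
#'   and `log`.
#' @export
merge_repeated_columns <- function(body, header_map, raw_header = NULL) {
  n <- length(header_map)
  seq_eq <- function(a, b) {
    length(a) == length(b) &&
      all((is.na(a) & is.na(b)) | (!is.na(a) & !is.na(b) & a == b))
  }
  block_len <- 0L
  for (b in seq_len(n %/% 2)) {
    if (n %% b != 0L) next
    k <- n %/% b
    blocks <- lapply(seq_len(k), function(i)
      header_map[((i - 1) * b + 1):(i * b)])
    if (!any(!is.na(blocks[[1]]))) next
    if (all(vapply(blocks[-1], seq_eq, logical(1), a = blocks[[1]]))) {
      block_len <- b
      break
    }
  }
  if (block_len == 0L || block_len == n) {
    return(list(body = body, header_map = header_map,
                raw_header = raw_header, merged = FALSE, log = list()))
  }
  k <- n %/% block_len
  stacked <- do.call(rbind, lapply(seq_len(k), function(i) {
    cols <- ((i - 1) * block_len + 1):(i * block_len)
    body[, cols, drop = FALSE]
  }))
  keep <- apply(stacked, 1, function(r) any(nzchar(r)))
  dropped <- sum(!keep)
  stacked <- stacked[keep, , drop = FALSE]
  list(body = stacked,
       header_map = header_map[seq_len(block_len)],
       raw_header = if (!is.null(raw_header)) raw_header[seq_len(block_len)],
       merged = TRUE,
       log = list(list(action = "merge_repeated_columns", k = k,
                       block_len = block_len, empty_rows_dropped = dropped)))
}

#' Flag drugs mentioned in text but absent from the table body
#'
#' Table extraction sometimes silently drops the final row; the document
#' text still names the drug. Any drug variant found (whole-word) in the
#' text whose canonical form appears in no body row raises the
#' `missing_row_suspected` flag and is listed for human review -- rows are
#' never synthesized automatically. Mentions inside a recognized test or
#' manufacturer name (e.g. the "Gentamicin" in "Charm Gentamicin") are
#' masked first: they name the assay, not a tested drug.
#'
#' @param body body matrix after repair.
#' @param header_map canonical field per column.
#' @param document_text full document text (may be empty).
#' @param lexicon an [default_lexicon()].
#' @return character vector of missing drug mentions (variant spellings as
#'   found in the text); empty when nothing is missing.
#' @export
detect_missing_rows <- function(body, header_map, document_text, lexicon) {
  if (!nzchar(document_text)) return(character(0))
  txt <- document_text
  for (tbl in list(lexicon$synonyms$test, lexicon$synonyms$manufacturer)) {
    ent <- find_entities(txt, tbl)
    for (i in seq_len(nrow(ent))) {
      span <- ent$start[i]:ent$end[i]
      substr(txt, ent$start[i], ent$end[i]) <-
        strrep(" ", length(span))
    }
  }
  mentions <- find_entities(txt, lexicon$synonyms$drug)
  if (!nrow(mentions)) return(character(0))
  drug_cols <- which(!is.na(header_map) & header_map == "Drug")
  body_cells <- if (length(drug_cols)) as.vector(body[, drug_cols]) else
    as.vector(body)
  body_canon <- vapply(body_cells, function(cell) {
    if (!nzchar(cell)) return(NA_character_)
    hit <- canonicalize_entity(split_method(cell)$name,
                               lexicon$synonyms$drug)
    if (is.null(hit)) NA_character_ else hit$canonical
  }, character(1), USE.NAMES = FALSE)
  body_canon <- unique(body_canon[!is.na(body_canon)])
  missing <- mentions[!(mentions$canonical %in% body_canon), , drop = FALSE]
  if (!nrow(missing)) return(character(0))
  # one mention per missing drug: the longest variant spelling found
  unname(vapply(split(missing$variant, missing$canonical),
                function(v) v[which.max(nchar(v))], character(1)))
}

#' Detect the concentration unit of a table
#'
#' `"ppb"` when any cell matches the ppb keyword, `"ppm"` when ppm matches
#' and ppb does not, `NA` otherwise. When both units appear the table-level
#' hint is withheld (units are then resolved per column at record-building
#' time) and the condition is logged.
#'
#' @param table a [raw_table()] or character matrix.
#' @param lexicon an [default_lexicon()].
#' @return `"ppb"`, `"ppm"` or `NA_character_`.
#' @export
detect_unit <- function(table, lexicon) {
  grid <- if (inherits(table, "raw_table")) table$grid else table
  blob <- paste(as.vector(grid), collapse = "\n")
  hits <- match_keyword(blob, lexicon$ensembles$unit)
  units <- unique(tolower(hits$match))
  if ("ppb" %in% units && "ppm" %in% units) {
    message("both ppb and ppm present; per-column unit resolution applies")
    return(NA_character_)
  }
  if ("ppb" %in% units) return("ppb")
  if ("ppm" %in% units) return("ppm")
  NA_character_
}

# Unit named in a single string (e.g. a header cell), or NA.
cell_unit <- function(text) {
  m <- regexpr("(?<!\\w)pp[bm](?!\\w)", text, perl = TRUE,
               ignore.case = TRUE)
  if (m[1] == -1L) NA_character_ else tolower(regmatches(text, m))
}

#' Run the full repair chain on a raw table
#'
#' Fixed order: banner removal above the header, header identification,
#' repeated-column merging, title-row removal, then missing-row detection
#' (combined pathologies compose in that order). Every removal is logged so
#' input rows always equal output rows plus logged removals.
#'
#' @param table a [raw_table()] (should already have passed
#'   [is_relevant()]).
#' @param lexicon an [default_lexicon()].
#' @param document_text full document text for missing-row detection
#'   (may be empty).
#' @return a `repaired_table`: list with `header` (canonical per column),
#'   `raw_header`, `body`, `unit_hint`, `flags`, `repair_log`, and
#'   provenance fields.
#' @export
repair_table <- function(table, lexicon, document_text = "") {
  stopifnot(inherits(table, "raw_table"))
  hd <- identify_header(table, lexicon$fields)
  cleaned <- drop_title_rows(table$grid, hd$index)
  flags <- cleaned$flags
  log <- cleaned$log
  raw_header <- unname(table$grid[hd$index, ])

  merged <- merge_repeated_columns(cleaned$body, hd$map, raw_header)
  if (merged$merged) {
    flags <- c(flags, "had_repeated_columns")
    log <- c(log, merged$log)
    # stacking can surface number-free rows (e.g. a title row that was
    # split across blocks); sweep them under the same rule
    post <- drop_title_rows(rbind(merged$raw_header, merged$body), 1L)
    log <- c(log, post$log)
    flags <- unique(c(flags, post$flags[post$flags != "had_banner"]))
    body <- post$body
  } else {
    body <- merged$body
  }

  unit_hint <- suppressMessages(detect_unit(table, lexicon))
  missing <- detect_missing_rows(body, merged$header_map, document_text,
                                 lexicon)
  if (length(missing)) {
    flags <- c(flags, "missing_row_suspected")
    log <- c(log, list(list(action = "missing_row_suspected",
                            drugs = missing)))
  }
  structure(list(header = merged$header_map,
                 raw_header = merged$raw_header %||% raw_header,
                 body = body, unit_hint = unit_hint,
                 flags = unique(flags), repair_log = log,
                 doc_id = table$doc_id, page = table$page,
                 page_title = table$page_title,
                 source_locator = table$source_locator),
            class = "repaired_table")
}

#' @export
print.repaired_table <- function(x, ...) {
  cat(sprintf("<repaired_table %dx%d doc=%s flags=[%s]>\n",
              nrow(x$body), ncol(x$body), x$doc_id,
              paste(x$flags, collapse = ", ")))
  invisible(x)
}
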