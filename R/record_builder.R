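# Converting repaired tables plus document context into normalized assay
# records. All concentrations are stored in ppb (1 ppm = 1000 ppb).

#' Parse a sensitivity cell
#'
#' Accepted grammar: a point value `"20"`, a range `"4-6"` (hyphen,
#' en/em-dash or "to"), a comparator prefix (`<=`/`≤` at-or-below,
#' `<` below, `>`/`>=`/`≥` at-or-above), thousands separators, and an
#' optional in-cell unit token (`ppb`/`ppm`). Unit precedence: in-cell
#' token, then the supplied hint, then ppb. ppm values are converted
#' (x 1000) so stored values are always ppb and strictly positive.
#'
#' @param cell non-empty cell string.
#' @param unit_hint `"ppb"`, `"ppm"` or `NA` (from [detect_unit()] or the
#'   column header).
#' @return list with `kind` ("point"/"range"), `low`, `high` (ppb,
#'   `high = low` for a point), `qualifier` ("none", "at_or_below",
#'   "below", "at_or_above"), `original_text`, `original_unit`
#'   ("ppb"/"ppm"/"unknown").
#' @export
#' @examples
#' parse_sensitivity("5 ppm")          # point, 5000 ppb
#' parse_sensitivity("4-6", "ppb")     # range 4..6 ppb
parse_sensitivity <- function(cell, unit_hint = NA_character_) {
  stopifnot(nzchar(cell))
  orig <- cell
  s <- trimws(cell)

  unit <- cell_unit(s)
  s <- trimws(gsub("(?<!\\w)pp[bm](?!\\w)", "", s, perl = TRUE,
                   ignore.case = TRUE))
  s <- trimws(gsub("[()]", "", s))

  qualifier <- "none"
  if (grepl("^(<=|≤)", s)) {
    qualifier <- "at_or_below"; s <- sub("^(<=|≤)", "", s)
  } else if (grepl("^<", s)) {
    qualifier <- "below"; s <- sub("^<", "", s)
  } else if (grepl("^(>=|≥|>)", s)) {
    qualifier <- "at_or_above"; s <- sub("^(>=|≥|>)", "", s)
  }
  s <- trimws(s)

  num <- "[0-9][0-9,]*(?:\\.[0-9]+)?|\\.[0-9]+"
  range_re <- sprintf("^(%s)\\s*(?:-|–|—|to)\\s*(%s)$", num, num)
  point_re <- sprintf("^(%s)$", num)
  val <- function(x) as.numeric(gsub(",", "", x))

  if (grepl(range_re, s, ignore.case = TRUE)) {
    m <- regmatches(s, regexec(range_re, s, ignore.case = TRUE))[[1]]
    low <- val(m[2]); high <- val(m[3]); kind <- "range"
  } else if (grepl(point_re, s)) {
    low <- high <- val(s); kind <- "point"
  } else {
    ah_error(sprintf("cannot parse sensitivity value: '%s'", orig),
             "assayharvest_parse_error")
  }

  effective <- if (!is.na(unit)) unit
               else if (!is.na(unit_hint)) unit_hint
               else "ppb"
  original_unit <- if (!is.na(unit)) unit
                   else if (!is.na(unit_hint)) unit_hint
                   else "unknown"
  factor <- if (identical(effective, "ppm")) 1000 else 1
  low <- low * factor; high <- high * factor
  if (!(low > 0) || high < low) {
    ah_error(sprintf("sensitivity out of range: '%s'", orig),
             "assayharvest_parse_error")
  }
  list(kind = kind, low = low, high = high, qualifier = qualifier,
       original_text = orig, original_unit = original_unit)
}

# Column index of the first column mapped to a canonical field, or NA.
field_col <- function(header_map, field) {
  idx <- which(!is.na(header_map) & header_map == field)
  if (length(idx)) idx[1] else NA_integer_
}

empty_records <- function() {
  tibble::tibble(drug = character(0), test = character(0),
                 matrix = character(0), assay_type = character(0),
                 animal = character(0), manufacturer = character(0),
                 sens_kind = character(0), sens_low_ppb = numeric(0),
                 sens_high_ppb = numeric(0), qualifier = character(0),
                 original_unit = character(0), mrl_ppb = numeric(0),
                 tolerance_ppb = numeric(0), source = character(0),
                 doc_id = character(0), page = integer(0),
                 doc_year = integer(0), doc_month = integer(0))
}

#' Build assay records from a repaired table
#'
#' One record per body row with a non-empty drug cell and a parseable
#' sensitivity. Drug, test and matrix are canonicalized through the synonym
#' tables; the assay type is taken from a Type column, else from a method
#' token split off the drug cell, else from the document context (in that
#' precedence). The matrix comes from a Matrix column, else from context.
#' MRL and Tolerance columns, when the source table carries them, are
#' captured rather than discarded. Rows that cannot be parsed are logged
#' and skipped, never silently dropped.
#'
#' @param repaired a [repair_table()] result.
#' @param context an [extract_context()] result (may be all-absent).
#' @param lexicon an [default_lexicon()].
#' @param doc list of per-document defaults and provenance: `year`,
#'   `month`, and optionally `animal`, `manufacturer`.
#' @return tibble of records (possibly zero rows) with attribute
#'   `"skipped"`: a list of `(row, reason)` entries.
#' @export
build_records <- function(repaired, context = NULL, lexicon,
                          doc = list()) {
  stopifnot(inherits(repaired, "repaired_table"))
  if (is.null(context)) {
    context <- list(matrix = NA_character_, test = NA_character_,
                    assay_type = NA_character_)
  }
  hm <- repaired$header
  body <- repaired$body
  skipped <- list()
  skip <- function(i, why) {
    skipped[[length(skipped) + 1L]] <<- list(row = i, reason = why)
    message(sprintf("row %d skipped (%s) in %s p%d", i, why,
                    repaired$doc_id, repaired$page))
  }

  drug_col <- field_col(hm, "Drug")
  sens_col <- field_col(hm, "Sensitivity")
  if (is.na(drug_col) || is.na(sens_col)) {
    warning(sprintf("table %s p%d has no Drug/Sensitivity columns; %s",
                    repaired$doc_id, repaired$page,
                    "no relevant fields"), call. = FALSE)
    out <- empty_records()
    attr(out, "skipped") <- skipped
    return(out)
  }
  # unit resolution: sensitivity column header beats the table-level hint
  col_unit <- cell_unit(repaired$raw_header[sens_col])
  unit_hint <- if (!is.na(col_unit)) col_unit else repaired$unit_hint

  parse_conc <- function(cell, what, i) {
    if (is_blank(cell)) return(NA_real_)
    v <- tryCatch(parse_sensitivity(cell, unit_hint),
                  assayharvest_parse_error = function(e) NULL)
    if (is.null(v)) { NA_real_ } else v$low
  }

  rows <- list()
  for (i in seq_len(nrow(body))) {
    drug_raw <- body[i, drug_col]
    if (is_blank(drug_raw)) { skip(i, "no drug"); next }
    sm <- split_method(drug_raw)
    if (!nzchar(sm$name)) { skip(i, "no drug"); next }
    drug_hit <- canonicalize_entity(sm$name, lexicon$synonyms$drug)
    if (is.null(drug_hit)) { skip(i, paste0("unknown drug: ", sm$name)); next }

    sens_cell <- body[i, sens_col]
    if (is_blank(sens_cell)) { skip(i, "no sensitivity"); next }
    sens <- tryCatch(parse_sensitivity(sens_cell, unit_hint),
                     assayharvest_parse_error = function(e) NULL)
    if (is.null(sens)) {
      skip(i, paste0("unparseable sensitivity: ", sens_cell)); next
    }

    test_col <- field_col(hm, "Test")
    test_raw <- if (!is.na(test_col) && !is_blank(body[i, test_col]))
      body[i, test_col] else context$test
    test_hit <- if (!is.null(test_raw) && !is.na(test_raw))
      canonicalize_entity(split_method(test_raw)$name,
                          lexicon$synonyms$test) else NULL
    if (is.null(test_hit)) { skip(i, "unresolved test name"); next }

    mat_col <- field_col(hm, "Matrix")
    mat_raw <- if (!is.na(mat_col) && !is_blank(body[i, mat_col]))
      body[i, mat_col] else context$matrix
    mat <- if (is.null(mat_raw) || is.na(mat_raw)) NA_character_ else {
      hit <- canonicalize_entity(mat_raw, lexicon$synonyms$matrix)
      if (is.null(hit)) mat_raw else hit$canonical
    }
    if (is.na(mat)) { skip(i, "no matrix"); next }

    type_col <- field_col(hm, "Type")
    type <- NA_character_
    if (!is.na(type_col) && !is_blank(body[i, type_col])) {
      tv <- tolower(trimws(body[i, type_col]))
      if (tv %in% lexicon$assay_types) type <- tv
    }
    if (is.na(type) && !is.na(sm$method)) type <- sm$method
    if (is.na(type) && !is.null(context$assay_type) &&
        !is.na(context$assay_type)) type <- context$assay_type
    if (is.na(type)) type <- "unknown"

    an_col <- field_col(hm, "Animal")
    animal <- if (!is.na(an_col) && !is_blank(body[i, an_col]))
      body[i, an_col] else doc$animal %||% NA_character_
    man_col <- field_col(hm, "Manufacturer")
    manufacturer <- if (!is.na(man_col) && !is_blank(body[i, man_col]))
      body[i, man_col] else doc$manufacturer %||% NA_character_

    mrl_col <- field_col(hm, "MRL")
    mrl <- if (!is.na(mrl_col)) parse_conc(body[i, mrl_col], "MRL", i)
           else NA_real_
    tol_col <- field_col(hm, "Tolerance")
    tol <- if (!is.na(tol_col)) parse_conc(body[i, tol_col], "Tolerance", i)
           else NA_real_

    rows[[length(rows) + 1L]] <- tibble::tibble(
      drug = drug_hit$canonical, test = test_hit$canonical, matrix = mat,
      assay_type = type, animal = animal, manufacturer = manufacturer,
      sens_kind = sens$kind, sens_low_ppb = sens$low,
      sens_high_ppb = sens$high, qualifier = sens$qualifier,
      original_unit = sens$original_unit, mrl_ppb = mrl,
      tolerance_ppb = tol, source = repaired$source_locator,
      doc_id = repaired$doc_id, page = repaired$page,
      doc_year = doc$year %||% NA_integer_,
      doc_month = doc$month %||% NA_integer_)
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    warning(sprintf("no parseable rows in table %s p%d",
                    repaired$doc_id, repaired$page), call. = FALSE)
    empty_records()
  }
  attr(out, "skipped") <- skipped
  out
}

#' Write records to the checkpoint CSV
#'
#' Column order: Drug, Test, Matrix, Type, Sensitivity_low_ppb,
#' Sensitivity_high_ppb, Qualifier, Animal, Manufacturer, MRL_ppb,
#' Tolerance_ppb, Source.
#'
#' @param records tibble from [build_records()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_records_csv <- function(records, path) {
  df <- data.frame(Drug = records$drug, Test = records$test,
                   Matrix = records$matrix, Type = records$assay_type,
                   Sensitivity_low_ppb = format_num(records$sens_low_ppb),
                   Sensitivity_high_ppb = format_num(records$sens_high_ppb),
                   Qualifier = records$qualifier, Animal = records$animal,
                   Manufacturer = records$manufacturer,
                   MRL_ppb = format_num(records$mrl_ppb),
                   Tolerance_ppb = format_num(records$tolerance_ppb),
                   Source = records$source, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8",
                   na = "")
  invisible(path)
}
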