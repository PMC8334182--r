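# Consolidating freshly mined records into the master datasheet.
# Key = (drug, test, matrix, assay_type); "unknown" type is a key value of
# its own so untyped rows never collide with typed ones.

MASTER_COLS <- c("drug", "test", "matrix", "assay_type",
                 "sens_low_ppb", "sens_high_ppb", "qualifier",
                 "animal", "manufacturer", "mrl_ppb", "tolerance_ppb",
                 "source", "last_updated")

EXPORT_COLS <- c(Drug = "drug", Test = "test", Matrix = "matrix",
                 Type = "assay_type",
                 Sensitivity_low_ppb = "sens_low_ppb",
                 Sensitivity_high_ppb = "sens_high_ppb",
                 Qualifier = "qualifier", Animal = "animal",
                 Manufacturer = "manufacturer", MRL_ppb = "mrl_ppb",
                 Tolerance_ppb = "tolerance_ppb", Source = "source",
                 Last_Updated = "last_updated")

record_key <- function(df) {
  paste(df$drug, df$test, df$matrix, df$assay_type, sep = "\x1f")
}

# Sensitivity equality for the update test: exact (low, high, qualifier)
# after unit normalization, with 1e-9 ppb float slack -- these are catalog
# numbers, not measurements.
sens_equal <- function(low1, high1, q1, low2, high2, q2) {
  abs(low1 - low2) <= 1e-9 && abs(high1 - high2) <= 1e-9 &&
    identical(q1 %||% "none", q2 %||% "none")
}

#' Create a master datasheet
#'
#' A keyed collection of assay records with upsert semantics. The key
#' (drug, test, matrix, assay type) must be unique.
#'
#' @param records optional tibble with the master columns (drug, test,
#'   matrix, assay_type, sens_low_ppb, sens_high_ppb, qualifier, animal,
#'   manufacturer, mrl_ppb, tolerance_ppb, source, last_updated).
#' @return a `master_sheet` object (a tibble subclass).
#' @export
master_sheet <- function(records = NULL) {
  if (is.null(records)) {
    records <- tibble::as_tibble(stats::setNames(
      list(character(0), character(0), character(0), character(0),
           numeric(0), numeric(0), character(0), character(0),
           character(0), numeric(0), numeric(0), character(0),
           character(0)),
      MASTER_COLS))
  }
  records <- tibble::as_tibble(records)[, MASTER_COLS]
  if (anyDuplicated(record_key(records))) {
    ah_error("duplicate (drug, test, matrix, type) key in master sheet",
             "assayharvest_key_error")
  }
  class(records) <- c("master_sheet", class(tibble::tibble()))
  records
}

#' Upsert mined records into the master sheet
#'
#' Per incoming record: key present with an equal sensitivity -> unchanged;
#' key present with a different sensitivity -> the sensitivity (and source)
#' are replaced and the old value logged; key absent -> the record is
#' appended. Two incoming records with the same key but different
#' sensitivities are a conflict: the later document (year, month) wins and
#' the loser is logged; a date tie is flagged for review.
#'
#' @param master a [master_sheet()].
#' @param incoming tibble of records from [build_records()] (canonical
#'   names; validated against `lexicon` when supplied).
#' @param lexicon optional [default_lexicon()] for canonical-name
#'   validation; non-canonical incoming names are a pipeline bug and raise
#'   an error.
#' @param now timestamp recorded on touched rows.
#' @return list with `master` (updated sheet) and `report` (a
#'   `reconcile_report`: `updated`, `inserted`, `unchanged`, `conflicts`).
#' @export
upsert <- function(master, incoming, lexicon = NULL, now = utc_now()) {
  stopifnot(inherits(master, "master_sheet"))
  incoming <- tibble::as_tibble(incoming)
  if (!is.null(lexicon) && nrow(incoming)) {
    ok_drug <- incoming$drug %in% names(lexicon$synonyms$drug$rows)
    ok_test <- incoming$test %in% names(lexicon$synonyms$test$rows)
    ok_mat <- incoming$matrix %in% names(lexicon$synonyms$matrix$rows)
    if (!all(ok_drug & ok_test & ok_mat)) {
      bad <- which(!(ok_drug & ok_test & ok_mat))[1]
      ah_error(sprintf("non-canonical incoming record: %s / %s / %s",
                       incoming$drug[bad], incoming$test[bad],
                       incoming$matrix[bad]),
               "assayharvest_canonical_error")
    }
  }

  conflicts <- list()
  if (nrow(incoming)) {
    keys <- record_key(incoming)
    keep <- rep(TRUE, nrow(incoming))
    for (k in unique(keys[duplicated(keys)])) {
      idx <- which(keys == k)
      lows <- incoming$sens_low_ppb[idx]
      highs <- incoming$sens_high_ppb[idx]
      quals <- incoming$qualifier[idx]
      all_eq <- all(vapply(idx[-1], function(j)
        sens_equal(lows[1], highs[1], quals[1],
                   incoming$sens_low_ppb[j], incoming$sens_high_ppb[j],
                   incoming$qualifier[j]), logical(1)))
      if (all_eq) {
        keep[idx[-1]] <- FALSE
        next
      }
      yr <- incoming$doc_year[idx] %||% rep(NA_integer_, length(idx))
      mo <- incoming$doc_month[idx] %||% rep(NA_integer_, length(idx))
      stamp <- ifelse(is.na(yr), -1, yr * 100 + ifelse(is.na(mo), 0, mo))
      winner <- idx[order(-stamp, seq_along(idx))][1]
      tie <- sum(stamp == max(stamp)) > 1
      conflicts[[length(conflicts) + 1L]] <- list(
        key = k, winner_row = winner,
        sensitivities = lows, needs_review = tie)
      keep[idx[idx != winner]] <- FALSE
    }
    suppressed <- sum(!keep)
    incoming <- incoming[keep, , drop = FALSE]
  } else {
    suppressed <- 0L
  }

  mkeys <- record_key(master)
  updated <- list(); inserted <- character(0); unchanged <- 0L
  for (i in seq_len(nrow(incoming))) {
    rec <- incoming[i, ]
    k <- record_key(rec)
    j <- match(k, mkeys)
    if (is.na(j)) {
      new_row <- tibble::tibble(
        drug = rec$drug, test = rec$test, matrix = rec$matrix,
        assay_type = rec$assay_type, sens_low_ppb = rec$sens_low_ppb,
        sens_high_ppb = rec$sens_high_ppb, qualifier = rec$qualifier,
        animal = rec$animal %||% NA_character_,
        manufacturer = rec$manufacturer %||% NA_character_,
        mrl_ppb = rec$mrl_ppb %||% NA_real_,
        tolerance_ppb = rec$tolerance_ppb %||% NA_real_,
        source = rec$source, last_updated = now)
      master <- master_sheet(rbind(tibble::as_tibble(master), new_row))
      mkeys <- c(mkeys, k)
      inserted <- c(inserted, k)
    } else if (sens_equal(master$sens_low_ppb[j], master$sens_high_ppb[j],
                          master$qualifier[j], rec$sens_low_ppb,
                          rec$sens_high_ppb, rec$qualifier)) {
      unchanged <- unchanged + 1L
    } else {
      updated[[length(updated) + 1L]] <- list(
        key = k, old_low = master$sens_low_ppb[j],
        old_high = master$sens_high_ppb[j],
        new_low = rec$sens_low_ppb, new_high = rec$sens_high_ppb,
        source = rec$source)
      master$sens_low_ppb[j] <- rec$sens_low_ppb
      master$sens_high_ppb[j] <- rec$sens_high_ppb
      master$qualifier[j] <- rec$qualifier
      master$source[j] <- rec$source
      master$last_updated[j] <- now
      if (!is.na(rec$mrl_ppb %||% NA_real_)) master$mrl_ppb[j] <- rec$mrl_ppb
    }
  }
  report <- structure(list(updated = updated, inserted = inserted,
                           unchanged = unchanged, conflicts = conflicts,
                           suppressed = suppressed),
                      class = "reconcile_report")
  list(master = master, report = report)
}

#' @export
print.reconcile_report <- function(x, ...) {
  cat(sprintf(
    "<reconcile_report: %d updated, %d inserted, %d unchanged, %d conflicts>\n",
    length(x$updated), length(x$inserted), x$unchanged,
    length(x$conflicts)))
  invisible(x)
}

#' Join FDA tolerances onto the master sheet
#'
#' Tolerances come from a user-supplied table keyed by canonical drug name
#' (they are curated from the federal regulations, not mined). When the
#' table has an entry for a record's drug it overrides; a record whose drug
#' is absent keeps whatever per-record tolerance its source table carried.
#' Records whose sensitivity floor exceeds the tolerance are flagged: such
#' a test cannot confirm compliance at the tolerance.
#'
#' @param master a [master_sheet()].
#' @param tolerance_table named numeric vector (drug -> tolerance ppb) or a
#'   data frame with columns `drug`, `tolerance_ppb`.
#' @param lexicon optional; non-canonical drug names in the table are
#'   skipped with a warning.
#' @return list with `master` and `flagged` (tibble of keys where
#'   sensitivity exceeds tolerance).
#' @export
join_tolerance <- function(master, tolerance_table, lexicon = NULL) {
  stopifnot(inherits(master, "master_sheet"))
  if (is.data.frame(tolerance_table)) {
    tol <- stats::setNames(as.numeric(tolerance_table$tolerance_ppb),
                           tolerance_table$drug)
  } else {
    tol <- tolerance_table
  }
  if (!is.null(lexicon)) {
    bad <- setdiff(names(tol), names(lexicon$synonyms$drug$rows))
    if (length(bad)) {
      warning(sprintf("non-canonical drug(s) in tolerance table skipped: %s",
                      paste(bad, collapse = ", ")), call. = FALSE)
      tol <- tol[setdiff(names(tol), bad)]
    }
  }
  hit <- match(master$drug, names(tol))
  master$tolerance_ppb <- ifelse(is.na(hit), master$tolerance_ppb,
                                 unname(tol[hit]))
  exceeds <- !is.na(master$tolerance_ppb) &
    master$sens_low_ppb > master$tolerance_ppb
  flagged <- tibble::tibble(
    drug = master$drug[exceeds], test = master$test[exceeds],
    matrix = master$matrix[exceeds], assay_type = master$assay_type[exceeds],
    sens_low_ppb = master$sens_low_ppb[exceeds],
    tolerance_ppb = master$tolerance_ppb[exceeds],
    flag = rep("sensitivity exceeds tolerance", sum(exceeds)))
  list(master = master_sheet(master), flagged = flagged)
}

#' Export the master sheet
#'
#' Deterministic CSV (UTF-8, quoted strings, rows in key-lexicographic
#' order): two exports of the same sheet are byte-identical, and the file
#' round-trips losslessly through [read_master()]. The xlsx format listed
#' by some consumers is not written by this package; requesting it raises
#' an error.
#'
#' @param master a [master_sheet()].
#' @param path output path.
#' @param format `"csv"` (supported) or `"xlsx"` (rejected).
#' @return `path`, invisibly.
#' @export
export_master <- function(master, path, format = c("csv", "xlsx")) {
  format <- match.arg(format)
  if (format == "xlsx") {
    ah_error("xlsx export is not supported; use csv",
             "assayharvest_io_error")
  }
  stopifnot(inherits(master, "master_sheet"))
  ord <- order(record_key(master), method = "radix")
  m <- tibble::as_tibble(master)[ord, ]
  df <- as.data.frame(lapply(EXPORT_COLS, function(col) {
    v <- m[[col]]
    if (is.numeric(v)) format_num(v) else v
  }), optional = TRUE, stringsAsFactors = FALSE)
  names(df) <- names(EXPORT_COLS)
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, na = "", eol = "\n")
  invisible(path)
}

#' @rdname export_master
#' @export
read_master <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                        colClasses = "character", fileEncoding = "UTF-8")
  m <- stats::setNames(df, MASTER_COLS[match(names(df),
                                             names(EXPORT_COLS))])
  for (col in c("sens_low_ppb", "sens_high_ppb", "mrl_ppb",
                "tolerance_ppb")) {
    m[[col]] <- as.numeric(m[[col]])
  }
  for (col in MASTER_COLS) if (is.null(m[[col]])) m[[col]] <- NA_character_
  master_sheet(tibble::as_tibble(m))
}

#' Write a reconcile report as JSON
#'
#' @param report a `reconcile_report` from [upsert()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reconcile_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
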