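# Harvesting candidate documents from a year/month directory hierarchy.
# Manufacturers publish datasheets under <root>/<YYYY>/<MM>/<file>; the
# relevant files carry "MRK" (any letter casing) in the filename.

#' Enumerate candidate documents in a year/month listing
#'
#' Walks `<root>/<YYYY>/<MM>/` for the requested years and returns one
#' reference per file whose name contains the substring "mrk" after case
#' folding (so "MRK", "mRK", "MrK", ... are all accepted). Order is
#' deterministic: year, month, then filename. Month directories are not
#' filtered; all months within a requested year are scanned.
#'
#' @param root directory whose children are 4-digit year directories.
#' @param years integer vector of years to include (non-empty).
#' @return tibble with columns `doc_id`, `source_locator`, `kind`
#'   ("pdf"/"html" from the extension), `year`, `month`, `filename`.
#'   A requested year with no directory is skipped with a warning.
#' @export
#' @examples
#' \dontrun{
#' refs <- enumerate_listing("corpus", 2018:2020)
#' }
enumerate_listing <- function(root, years) {
  stopifnot(length(years) > 0)
  if (!dir.exists(root)) {
    ah_error(sprintf("listing root not reachable: %s", root),
             "assayharvest_retrieval_error", locator = root)
  }
  rows <- list()
  for (y in sort(as.integer(years))) {
    ydir <- file.path(root, sprintf("%04d", y))
    if (!dir.exists(ydir)) {
      warning(sprintf("year directory absent, skipped: %s", ydir),
              call. = FALSE)
      next
    }
    months <- list.dirs(ydir, recursive = FALSE, full.names = FALSE)
    months <- months[grepl("^[0-9]{1,2}$", months)]
    for (mdir in months[order(as.integer(months))]) {
      m <- as.integer(mdir)
      files <- sort(list.files(file.path(ydir, mdir)), method = "radix")
      files <- files[grepl("mrk", tolower(files), fixed = TRUE)]
      for (f in files) {
        ext <- tolower(tools::file_ext(f))
        kind <- if (ext == "pdf") "pdf"
                else if (ext %in% c("html", "htm")) "html"
                else NA_character_
        if (is.na(kind)) {
          warning(sprintf("unsupported document type, skipped: %s", f),
                  call. = FALSE)
          next
        }
        rows[[length(rows) + 1L]] <- tibble::tibble(
          doc_id = sprintf("%04d-%02d-%s", y, m, f),
          source_locator = file.path(ydir, mdir, f),
          kind = kind, year = y, month = m, filename = f
        )
      }
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(doc_id = character(0),
                          source_locator = character(0),
                          kind = character(0), year = integer(0),
                          month = integer(0), filename = character(0)))
  }
  do.call(rbind, rows)
}

#' Fetch a document into the local store
#'
#' Persists the bytes under `<store>/<YYYY>/<MM>/<filename>` and compares
#' content hashes so a re-fetch of an unchanged document is a no-op. A
#' changed document is overwritten and reported so downstream extraction
#' can be redone (the real-time update path).
#'
#' @param ref one row of [enumerate_listing()] output (tibble or list).
#' @param store root directory of the local document store.
#' @return the ref as a one-row tibble with added `sha256`, `stored_path`,
#'   `retrieved_at` and `status` ("stored", "unchanged" or "changed").
#' @export
fetch_document <- function(ref, store) {
  ref <- as.list(ref)
  src <- ref$source_locator
  size <- file.info(src)$size
  if (is.na(size)) {
    ah_error(sprintf("cannot read document: %s", src),
             "assayharvest_retrieval_error", locator = src)
  }
  bytes <- readBin(src, "raw", n = size)
  sha <- paste0(as.character(openssl::sha256(bytes)))
  dest_dir <- file.path(store, sprintf("%04d", ref$year),
                        sprintf("%02d", ref$month))
  dir.create(dest_dir, recursive = TRUE, showWarnings = FALSE)
  dest <- file.path(dest_dir, ref$filename)
  if (!file.exists(dest)) {
    writeBin(bytes, dest)
    status <- "stored"
  } else {
    old <- paste0(as.character(openssl::sha256(
      readBin(dest, "raw", n = file.info(dest)$size))))
    if (identical(old, sha)) {
      status <- "unchanged"
    } else {
      writeBin(bytes, dest)
      status <- "changed"
    }
  }
  tibble::tibble(doc_id = ref$doc_id, source_locator = src,
                 kind = ref$kind, year = ref$year, month = ref$month,
                 filename = ref$filename, sha256 = sha,
                 stored_path = dest, retrieved_at = utc_now(),
                 status = status)
}

#' Harvest a listing into a local store
#'
#' [enumerate_listing()] + [fetch_document()] for every accepted file.
#'
#' @inheritParams enumerate_listing
#' @param store local store directory.
#' @return manifest tibble (one fetched row per document).
#' @export
harvest_documents <- function(root, years, store) {
  refs <- enumerate_listing(root, years)
  if (!nrow(refs)) return(refs)
  out <- lapply(seq_len(nrow(refs)), function(i)
    fetch_document(refs[i, ], store))
  do.call(rbind, out)
}

#' Write/read the harvest manifest
#'
#' CSV columns: doc_id, locator, kind, year, month, filename, sha256,
#' retrieved_at.
#'
#' @param manifest tibble from [harvest_documents()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  df <- data.frame(doc_id = manifest$doc_id,
                   locator = manifest$source_locator,
                   kind = manifest$kind, year = manifest$year,
                   month = manifest$month, filename = manifest$filename,
                   sha256 = manifest$sha256,
                   retrieved_at = manifest$retrieved_at,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
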