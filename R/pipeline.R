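# Orchestration: harvest -> extract -> repair -> build -> reconcile, with
# checkpoints after each stage so the stages are independently inspectable
# and a rerun on unchanged inputs is a no-op on the master.

#' Pipeline configuration
#'
#' @param root document listing root (`<root>/<YYYY>/<MM>/<file>`).
#' @param out_dir working/output directory (store, checkpoints, master).
#' @param years years to harvest.
#' @param master_path prior master CSV; default: `<out_dir>/master.csv`
#'   when it exists (which makes reruns idempotent), else an empty master.
#' @param tolerance_path optional CSV `drug,tolerance_ppb` keyed by
#'   canonical drug names.
#' @param lexicon an [default_lexicon()].
#' @param extractor GridExtractor for PDF-kind documents.
#' @param verbose print stage progress.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(root, out_dir, years = 2018:2020,
                            master_path = NULL, tolerance_path = NULL,
                            lexicon = default_lexicon(),
                            extractor = json_grid_extractor,
                            verbose = FALSE) {
  if (!dir.exists(root)) {
    ah_error(sprintf("pipeline root does not exist: %s", root),
             "assayharvest_config_error")
  }
  if (!is.null(tolerance_path) && !file.exists(tolerance_path)) {
    ah_error(sprintf("tolerance table not found: %s", tolerance_path),
             "assayharvest_config_error")
  }
  structure(list(root = root, out_dir = out_dir, years = years,
                 master_path = master_path,
                 tolerance_path = tolerance_path, lexicon = lexicon,
                 extractor = extractor, verbose = verbose),
            class = "pipeline_config")
}

#' Run the mining pipeline
#'
#' Executes harvest, extraction, repair, record building and
#' reconciliation in order, writing checkpoints (`manifest.csv`,
#' `tables.jsonl`, `quarantine.jsonl`, `records.csv`, `master.csv`,
#' `report.json`) under the configured output directory. The mining itself
#' is deterministic; a second run over unchanged inputs produces zero
#' updates and zero inserts.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list with `report` (stage counts), `master`,
#'   `records`, `manifest`, `flagged_docs`.
#' @export
#' @examples
#' \dontrun{
#' corpus <- generate_corpus(fixture_spec(seed = 7), "work")
#' res <- run_pipeline(pipeline_config(corpus$root, "work/out"))
#' res$report
#' }
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  lex <- config$lexicon
  say <- function(...) if (config$verbose) message(sprintf(...))

  ## harvest
  manifest <- harvest_documents(config$root, config$years,
                                file.path(out, "store"))
  say("harvested %d documents", nrow(manifest))
  if (nrow(manifest)) write_manifest(manifest, file.path(out, "manifest.csv"))

  ## extract + repair + build
  all_tables <- list()
  quarantine <- list()
  records <- empty_records()
  tables_found <- 0L; tables_relevant <- 0L; tables_parsed <- 0L
  flagged_docs <- character(0)
  for (i in seq_len(nrow(manifest))) {
    ref <- manifest[i, ]
    doc <- tryCatch(read_document(ref, config$extractor),
                    assayharvest_extraction_error = function(e) {
                      warning(conditionMessage(e), call. = FALSE)
                      NULL
                    })
    if (is.null(doc)) next
    all_tables <- c(all_tables, doc$tables)
    tables_found <- tables_found + length(doc$tables)
    if (!length(doc$tables)) next
    context <- extract_context(doc$text, lex, page_title = doc$title,
                               url = ref$source_locator)
    for (tbl in doc$tables) {
      if (!is_relevant(tbl, lex)) next
      tables_relevant <- tables_relevant + 1L
      rep_tbl <- tryCatch(
        suppressMessages(repair_table(tbl, lex, document_text = doc$text)),
        assayharvest_header_error = function(e) e,
        assayharvest_repair_error = function(e) e)
      if (inherits(rep_tbl, "condition")) {
        quarantine[[length(quarantine) + 1L]] <- list(
          doc_id = ref$doc_id, page = NA, reason = conditionMessage(rep_tbl))
        next
      }
      tables_parsed <- tables_parsed + 1L
      if ("missing_row_suspected" %in% rep_tbl$flags) {
        flagged_docs <- union(flagged_docs, ref$doc_id)
      }
      recs <- suppressMessages(suppressWarnings(
        build_records(rep_tbl, context, lex,
                      doc = list(year = ref$year, month = ref$month))))
      if (nrow(recs)) records <- rbind(records, recs)
    }
  }
  say("%d/%d tables relevant, %d parsed, %d records",
      tables_relevant, tables_found, tables_parsed, nrow(records))
  if (length(all_tables)) {
    write_tables_jsonl(all_tables, file.path(out, "tables.jsonl"))
  }
  if (length(quarantine)) {
    writeLines(vapply(quarantine, function(q)
      as.character(jsonlite::toJSON(q, auto_unbox = TRUE, na = "null")),
      character(1)), file.path(out, "quarantine.jsonl"))
  }
  if (nrow(records)) {
    write_records_csv(records, file.path(out, "records.csv"))
  }

  ## reconcile
  master_path <- config$master_path %||% file.path(out, "master.csv")
  master <- if (file.exists(master_path)) read_master(master_path)
            else master_sheet()
  res <- upsert(master, records, lexicon = lex)
  master <- res$master
  flagged_tol <- NULL
  if (!is.null(config$tolerance_path)) {
    tol <- utils::read.csv(config$tolerance_path, stringsAsFactors = FALSE)
    jt <- join_tolerance(master, tol, lexicon = lex)
    master <- jt$master
    flagged_tol <- jt$flagged
  }
  export_master(master, file.path(out, "master.csv"))
  write_reconcile_report(res$report, file.path(out, "reconcile_report.json"))

  report <- list(
    documents = nrow(manifest),
    tables_found = tables_found,
    tables_relevant = tables_relevant,
    tables_parsed = tables_parsed,
    records = nrow(records),
    inserts = length(res$report$inserted),
    updates = length(res$report$updated),
    unchanged = res$report$unchanged,
    conflicts = length(res$report$conflicts),
    quarantined = length(quarantine),
    missing_row_docs = flagged_docs,
    tolerance_flags = if (is.null(flagged_tol)) 0L else nrow(flagged_tol))
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(report = report, master = master, records = records,
                 manifest = manifest, flagged_docs = flagged_docs,
                 reconcile = res$report, tolerance_flags = flagged_tol))
}
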