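# Seeded synthetic corpus: HTML and JSON page-grid documents exhibiting the
# documented extraction pathologies, with ground-truth records, so the whole
# pipeline is testable with no network access.

PATHOLOGIES <- c("clean", "missing_last_row", "multi_title",
                 "repeated_columns", "combined", "irrelevant")

# Case variants of the harvest filename marker.
MRK_VARIANTS <- c("mrk", "mrK", "mRk", "mRK", "Mrk", "MrK", "MRk", "MRK")

#' Specification of a synthetic corpus
#'
#' The defaults are the package's reference study conditions: 50 documents
#' mixing clean tables with the four structural pathologies and irrelevant
#' documents in proportion 40 : 15 : 15 : 15 : 15 : 15 (normalized),
#' drug/test/matrix pools drawn from the controlled vocabularies,
#' sensitivities 5-150 ppb, and a 80/20 ppb/ppm unit mix. The seed fully
#' determines the corpus.
#'
#' @param seed integer seed.
#' @param n_documents number of harvestable documents.
#' @param pathology_mix named numeric over
#'   clean/missing_last_row/multi_title/repeated_columns/combined/irrelevant;
#'   normalized to sum to 1.
#' @param sensitivity_range low/high bounds (ppb) for generated values.
#' @param unit_mix named proportions for ppb/ppm documents.
#' @param n_decoys number of non-matching decoy filenames scattered in the
#'   tree.
#' @return a `fixture_spec` object.
#' @export
fixture_spec <- function(seed, n_documents = 50L,
                         pathology_mix = c(clean = 40, missing_last_row = 15,
                                           multi_title = 15,
                                           repeated_columns = 15,
                                           combined = 15, irrelevant = 15),
                         sensitivity_range = c(5, 150),
                         unit_mix = c(ppb = 0.8, ppm = 0.2),
                         n_decoys = 6L) {
  stopifnot(setequal(names(pathology_mix), PATHOLOGIES),
            all(pathology_mix >= 0), sum(pathology_mix) > 0,
            n_documents >= length(PATHOLOGIES),
            sensitivity_range[1] > 0,
            sensitivity_range[2] >= sensitivity_range[1])
  pathology_mix <- pathology_mix[PATHOLOGIES] / sum(pathology_mix)
  structure(list(seed = as.integer(seed),
                 n_documents = as.integer(n_documents),
                 pathology_mix = pathology_mix,
                 sensitivity_range = sensitivity_range,
                 unit_mix = unit_mix / sum(unit_mix),
                 n_decoys = as.integer(n_decoys)),
            class = "fixture_spec")
}

#' Corrupt a clean table grid with one pathology
#'
#' Emulates what table extraction does to real documents:
#' `missing_last_row` deletes the final body row from the grid only (the
#' accompanying text still names the drug); `multi_title` inserts a
#' number-free drug-class title row mid-body and a banner row above the
#' header; `repeated_columns` splits the body rows into two halves placed
#' side by side under duplicated headers (odd counts pad the right block
#' with an empty row); `combined` composes multi_title then
#' repeated_columns.
#'
#' @param grid character matrix: header row 1, body below, >= 3 body rows.
#' @param pathology one of `"missing_last_row"`, `"multi_title"`,
#'   `"repeated_columns"`, `"combined"` (`"clean"` returns the grid
#'   unchanged).
#' @param title_row_text drug-class title inserted by multi_title.
#' @param banner_text banner headline inserted above the header.
#' @return the corrupted character matrix.
#' @export
corrupt_table <- function(grid, pathology,
                          title_row_text = "Beta-lactams",
                          banner_text = "Rapid Residue Screening Datasheet") {
  pathology <- match.arg(pathology, PATHOLOGIES)
  if (pathology %in% c("clean", "irrelevant")) return(grid)
  if (nrow(grid) < 4) {
    ah_error("need at least 3 body rows to corrupt a table",
             "assayharvest_fixture_error")
  }
  pad_row <- function(text) c(text, rep("", ncol(grid) - 1))
  if (pathology == "missing_last_row") {
    return(grid[-nrow(grid), , drop = FALSE])
  }
  if (pathology == "multi_title") {
    body <- grid[-1, , drop = FALSE]
    mid <- nrow(body) %/% 2
    out <- rbind(pad_row(banner_text), grid[1, , drop = FALSE],
                 body[seq_len(mid), , drop = FALSE],
                 pad_row(title_row_text),
                 body[seq_len(nrow(body)) > mid, , drop = FALSE])
    return(out)
  }
  if (pathology == "repeated_columns") {
    header <- grid[1, , drop = FALSE]
    body <- grid[-1, , drop = FALSE]
    nl <- ceiling(nrow(body) / 2)
    left <- body[seq_len(nl), , drop = FALSE]
    right <- body[seq_len(nrow(body)) > nl, , drop = FALSE]
    while (nrow(right) < nrow(left)) {
      right <- rbind(right, rep("", ncol(body)))
    }
    return(rbind(cbind(header, header), cbind(left, right)))
  }
  # combined: title rows first, then the side-by-side split (the banner is
  # re-attached above the doubled header)
  with_titles <- corrupt_table(grid, "multi_title",
                               title_row_text = title_row_text,
                               banner_text = banner_text)
  banner <- with_titles[1, , drop = FALSE]
  rest <- with_titles[-1, , drop = FALSE]
  split <- corrupt_table(rest, "repeated_columns")
  rbind(cbind(banner, banner), split)
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

render_html_doc <- function(title, text, grid) {
  rows <- if (is.null(grid)) "" else paste(vapply(seq_len(nrow(grid)),
    function(r) paste0("<tr>", paste0("<td>", html_escape(grid[r, ]),
                                      "</td>", collapse = ""), "</tr>"),
    character(1)), collapse = "\n")
  tbl <- if (is.null(grid)) "" else paste0("<table>\n", rows, "\n</table>")
  paste0("<html><head><meta charset=\"utf-8\"/><title>",
         html_escape(title), "</title></head>\n",
         "<body>\n<p>", html_escape(text), "</p>\n", tbl, "\n</body></html>\n")
}

render_json_doc <- function(title, text, grid, table_page = 1L) {
  n_pages <- max(1L, table_page)
  pages <- lapply(seq_len(n_pages), function(i) {
    list(text = if (i == 1L) text else "",
         tables = if (!is.null(grid) && i == table_page)
           list(apply(grid, 1, as.list, simplify = FALSE)) else list())
  })
  jsonlite::toJSON(list(title = title, pages = pages), auto_unbox = TRUE,
                   null = "null", pretty = TRUE)
}

# Surface spellings a generated document may use for its header cells.
DRUG_HEADERS <- c("Drug", "Antimicrobial drug", "Active ingredient",
                  "Residues detected", "Antimicrobial agent")
SENS_HEADERS <- c("Sensitivity", "Detection level", "Concentration",
                  "Positive Concentration", "Test Sensitivity",
                  "Detection range")
TOL_HEADERS <- c("Safe level", "Action Level")
TITLE_CLASSES <- c("Beta-lactams", "Tetracyclines", "Sulfonamides",
                   "Aminoglycosides", "Macrolides")
BANNERS <- c("Rapid Residue Screening Datasheet",
             "Approved for distribution in the USA and Canada",
             "Dairy Quality Program")

#' Generate a seeded ground-truth corpus
#'
#' Writes documents into a `<out_dir>/corpus/<YYYY>/<MM>/` tree with
#' filenames carrying case-varied "mrk" markers (plus decoy filenames the
#' harvester must reject), a `truth.csv` of the records each document
#' encodes, and an `expected_flags.json` of the repair flags each document
#' should raise. The same seed produces a byte-identical corpus.
#'
#' Each relevant document advertises one assay test (unique per corpus) on
#' one matrix, lists its drugs and sensitivities in a single table, and
#' mentions the tested drugs in the body text -- which is what makes
#' missing-row detection possible. Truth rows carry `in_grid = FALSE` for
#' rows a pathology removed from the grid (still named in the text).
#'
#' @param spec a [fixture_spec()].
#' @param out_dir output directory (created if needed).
#' @param lexicon lexicon supplying the vocabulary pools.
#' @return a `ground_truth_corpus`: list with `documents` (tibble),
#'   `truth` (tibble), `expected_flags` (named list), `root`,
#'   `truth_path`, `flags_path`.
#' @export
#' @examples
#' \dontrun{
#' corpus <- generate_corpus(fixture_spec(seed = 7, n_documents = 10),
#'                           tempfile())
#' }
generate_corpus <- function(spec, out_dir, lexicon = default_lexicon()) {
  stopifnot(inherits(spec, "fixture_spec"))
  root <- file.path(out_dir, "corpus")
  dir.create(root, recursive = TRUE, showWarnings = FALSE)

  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(spec$seed)

  n <- spec$n_documents
  counts <- apportion(n, spec$pathology_mix)
  pathology <- sample(rep(PATHOLOGIES, counts))

  drug_pool <- names(lexicon$synonyms$drug$rows)
  test_pool <- setdiff(names(lexicon$synonyms$test$rows),
                       grep(",", names(lexicon$synonyms$test$rows),
                            value = TRUE))
  # a test name carrying a matrix word (e.g. "... Milk Test") would
  # override the document's own matrix during context inference
  test_pool <- test_pool[vapply(test_pool, function(t)
    nrow(match_keyword(t, lexicon$ensembles$matrix)) == 0, logical(1))]
  matrix_pool <- c("Milk", "Serum", "Urine", "Honey")
  matrix_word <- c(Milk = "milk", Serum = "serum", Urine = "urine",
                   Honey = "honey")
  tests <- sample(test_pool, n, replace = FALSE)

  docs <- list(); truth <- list(); expected_flags <- list()
  for (i in seq_len(n)) {
    pat <- pathology[i]
    year <- sample(2018:2020, 1)
    month <- sample(1:12, 1)
    kind <- if (i %% 2 == 0) "pdf" else "html"
    test_name <- tests[i]
    slug <- tolower(gsub("[^A-Za-z0-9]+", "-", test_name))
    fname <- paste0(MRK_VARIANTS[(i - 1L) %% 8L + 1L], "-", slug, ".",
                    if (kind == "pdf") "pdf" else "html")
    dir <- file.path(root, sprintf("%04d", year), sprintf("%02d", month))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    path <- file.path(dir, fname)
    doc_id <- sprintf("%04d-%02d-%s", year, month, fname)

    if (pat == "irrelevant") {
      nav <- matrix(c("Home", "Products", "Support",
                      "About us", "Contact", "News"),
                    nrow = 2, byrow = TRUE)
      text <- "Thank you for visiting our product catalog."
      content <- if (kind == "html")
        render_html_doc("Product catalog", text,
                        if (i %% 4 == 1) nav else NULL)
      else render_json_doc("Product catalog", text,
                           if (i %% 4 == 0) nav else NULL)
      writeLines(content, path, useBytes = TRUE)
      docs[[i]] <- tibble::tibble(doc_id = doc_id, filename = fname,
                                  kind = kind, year = year, month = month,
                                  pathology = pat, test = NA_character_)
      expected_flags[[doc_id]] <- character(0)
      next
    }

    mat <- sample(matrix_pool, 1)
    type <- sample(c(lexicon$assay_types, NA_character_), 1)
    unit <- sample(names(spec$unit_mix), 1, prob = spec$unit_mix)
    n_drugs <- sample(5:8, 1)
    drugs <- sample(drug_pool, n_drugs)

    lo <- spec$sensitivity_range[1]; hi <- spec$sensitivity_range[2]
    sens_low <- sample(seq(lo, hi, by = 5), n_drugs, replace = TRUE)
    is_range <- stats::runif(n_drugs) < 0.15
    sens_high <- ifelse(is_range, sens_low + sample(5:20, n_drugs,
                                                    replace = TRUE),
                        sens_low)
    qualifier <- ifelse(!is_range & stats::runif(n_drugs) < 0.1,
                        "at_or_below", "none")
    with_tol <- stats::runif(1) < 0.3
    tol_vals <- if (with_tol) sens_low + sample(seq(50, 200, 50), n_drugs,
                                                replace = TRUE) else NULL

    # surface forms: occasionally a variant spelling, occasionally the
    # method word embedded comma-separated in the drug cell
    surface <- vapply(drugs, function(d) {
      vars <- lexicon$synonyms$drug$rows[[d]]
      if (length(vars) > 1 && stats::runif(1) < 0.3)
        sample(vars[-1], 1) else d
    }, character(1))
    drug_cells <- surface
    if (!is.na(type)) {
      embed <- stats::runif(n_drugs) < 0.2
      drug_cells[embed] <- ifelse(stats::runif(sum(embed)) < 0.5,
                                  paste0(surface[embed], ", ", type),
                                  paste0(type, ", ", surface[embed]))
    }

    fmt_val <- function(low, high, q) {
      show <- function(v) {
        v <- if (unit == "ppm") v / 1000 else v
        format(v, scientific = FALSE, trim = TRUE, drop0trailing = TRUE)
      }
      pre <- if (q == "at_or_below") "≤" else ""
      if (high > low) paste0(show(low), "-", show(high))
      else paste0(pre, show(low))
    }
    sens_cells <- mapply(fmt_val, sens_low, sens_high, qualifier)

    header <- c(sample(DRUG_HEADERS, 1),
                paste0(sample(SENS_HEADERS, 1),
                       sample(c(paste0(" (", unit, ")"),
                                paste0(" ", unit)), 1)))
    body <- cbind(drug_cells, sens_cells)
    if (with_tol) {
      header <- c(header, paste(sample(TOL_HEADERS, 1)))
      body <- cbind(body, vapply(tol_vals, function(v)
        format(if (unit == "ppm") v / 1000 else v, scientific = FALSE,
               trim = TRUE, drop0trailing = TRUE), character(1)))
    }
    grid <- rbind(header, unname(body))

    corrupted <- corrupt_table(grid, pat,
                               title_row_text = sample(TITLE_CLASSES, 1),
                               banner_text = sample(BANNERS, 1))

    sent <- c(sprintf(paste0("The %s test rapidly detects antimicrobial ",
                             "residues in %s at or below established ",
                             "tolerance and safe levels."),
                      test_name, matrix_word[[mat]]),
              if (!is.na(type)) sprintf("It is a %s assay.", type),
              sprintf("Compounds evaluated: %s.",
                      paste(surface, collapse = ", ")))
    text <- paste(sent, collapse = " ")
    title <- if (grepl("test$", tolower(test_name))) test_name
             else paste(test_name, "Test")

    content <- if (kind == "html") render_html_doc(title, text, corrupted)
               else render_json_doc(title, text, corrupted,
                                    table_page = if (i %% 6 == 0) 2L else 1L)
    writeLines(content, path, useBytes = TRUE)

    in_grid <- rep(TRUE, n_drugs)
    if (pat == "missing_last_row") in_grid[n_drugs] <- FALSE
    truth[[length(truth) + 1L]] <- tibble::tibble(
      doc_id = doc_id, drug = drugs, test = test_name, matrix = mat,
      assay_type = ifelse(is.na(type), "unknown", type),
      sens_low_ppb = as.numeric(sens_low),
      sens_high_ppb = as.numeric(sens_high),
      qualifier = qualifier,
      tolerance_ppb = if (with_tol) as.numeric(tol_vals) else NA_real_,
      unit = unit, in_grid = in_grid)
    expected_flags[[doc_id]] <- switch(
      pat,
      clean = character(0),
      missing_last_row = "missing_row_suspected",
      multi_title = c("had_banner", "had_title_rows"),
      repeated_columns = "had_repeated_columns",
      combined = c("had_banner", "had_title_rows", "had_repeated_columns"))
    docs[[i]] <- tibble::tibble(doc_id = doc_id, filename = fname,
                                kind = kind, year = year, month = month,
                                pathology = pat, test = test_name)
  }

  # decoys: no "mrk" substring, must be rejected by the harvest filter
  decoy_names <- paste0(c("report-", "overview-", "catalog-", "notes-",
                          "press-", "index-")[
                          seq_len(spec$n_decoys) %% 6 + 1],
                        seq_len(spec$n_decoys),
                        rep(c(".pdf", ".html"), length.out = spec$n_decoys))
  for (d in decoy_names) {
    year <- sample(2018:2020, 1); month <- sample(1:12, 1)
    dir <- file.path(root, sprintf("%04d", year), sprintf("%02d", month))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    content <- if (grepl("\\.html$", d))
      render_html_doc("Archive", "Archived page.", NULL)
    else render_json_doc("Archive", "Archived page.", NULL)
    writeLines(content, file.path(dir, d), useBytes = TRUE)
  }

  documents <- do.call(rbind, docs)
  truth <- if (length(truth)) do.call(rbind, truth) else NULL
  truth_path <- file.path(out_dir, "truth.csv")
  utils::write.csv(truth, truth_path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  flags_path <- file.path(out_dir, "expected_flags.json")
  jsonlite::write_json(expected_flags, flags_path, auto_unbox = FALSE)
  structure(list(documents = documents, truth = truth,
                 expected_flags = expected_flags, root = root,
                 truth_path = truth_path, flags_path = flags_path,
                 decoys = decoy_names),
            class = "ground_truth_corpus")
}

#' @export
print.ground_truth_corpus <- function(x, ...) {
  cat(sprintf("<ground_truth_corpus: %d documents, %d truth records at %s>\n",
              nrow(x$documents),
              if (is.null(x$truth)) 0L else nrow(x$truth), x$root))
  invisible(x)
}
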