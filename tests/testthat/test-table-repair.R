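test_that("relevance needs a desired-field keyword and a drug mention", {
  good <- mk_raw(mk_grid(c("Penicillin", "Tylosin", "Neomycin"),
                         c(4, 50, 150),
                         sens_header = "Concentration for positive ppb"))
  expect_true(is_relevant(good, lex))
  nav <- mk_raw(matrix(c("Home", "Products", "About", "Contact"), 2, 2))
  expect_false(is_relevant(nav, lex))
  expect_false(is_relevant(mk_raw(matrix("", 1, 1)), lex))
  # drug names alone without a sensitivity-family keyword are not enough
  drugs_only <- mk_raw(matrix(c("Penicillin", "Tylosin"), 2, 1))
  expect_false(is_relevant(drugs_only, lex))
})

test_that("header row is found by maximal canonicalizable cells", {
  t1 <- mk_raw(mk_grid(c("Penicillin G", "Cephapirin"), c(4, 20)))
  hd <- identify_header(t1, lex$fields)
  expect_equal(hd$index, 1L)
  expect_equal(unname(hd$map), c("Drug", "Sensitivity"))
  # banner above the true header: exhaustive scoring picks row 2
  banner_grid <- rbind(c("Approved datasheet", ""), t1$grid)
  hd2 <- identify_header(mk_raw(banner_grid), lex$fields)
  expect_equal(hd2$index, 2L)
  # no canonicalizable row anywhere -> quarantine error
  expect_error(identify_header(mk_raw(matrix(c("a", "b"), 1)), lex$fields),
               class = "assayharvest_header_error")
})

test_that("title rows vanish, numeric rows and the header survive", {
  grid <- rbind(c("Blue ribbon banner", ""),
                c("Antimicrobial drug", "Concentration (ppb)"),
                c("Tetracyclines", ""),
                c("Penicillin G", "4"),
                c("Tetracycline", "100"))
  res <- drop_title_rows(grid, 2L)
  expect_equal(res$body[, 1], c("Penicillin G", "Tetracycline"))
  expect_setequal(res$flags, c("had_banner", "had_title_rows"))
  acts <- vapply(res$log, `[[`, character(1), "action")
  expect_equal(sum(acts == "remove_banner"), 1L)
  expect_equal(sum(acts == "remove_title_row"), 1L)
  # conservation: input body rows = output rows + logged removals
  expect_equal(nrow(grid) - 1L, nrow(res$body) + length(res$log))
})

test_that("no row containing a positive number is ever removed", {
  set.seed(303)
  for (i in 1:200) {
    n <- sample(3:9, 1)
    drugs <- sample(names(lex$synonyms$drug$rows), n)
    vals <- as.character(sample(c(1, 4, 20, 0.5, 1000), n, replace = TRUE))
    grid <- mk_grid(drugs, vals)
    n_titles <- sample(0:2, 1)
    for (k in seq_len(n_titles)) {
      at <- sample(2:nrow(grid), 1)
      grid <- rbind(grid[seq_len(at - 1), , drop = FALSE],
                    c(sample(c("Beta-lactams", "Sulfonamides"), 1), ""),
                    grid[seq_len(nrow(grid)) >= at, , drop = FALSE])
    }
    res <- drop_title_rows(grid, 1L)
    # every surviving row has a positive number; every removed one has none
    expect_true(all(apply(res$body, 1, assayharvest:::has_positive_number)))
    expect_equal(nrow(res$body), n)
    removed <- length(res$log)
    expect_equal(removed, n_titles)
  }
})

test_that("repeated column groups stack left block first", {
  base <- mk_grid(sprintf("drug%d", 1:5), 1:5)
  # manual side-by-side: 5 rows -> left 3, right 2 + empty pad
  split <- corrupt_table(base, "repeated_columns")
  expect_equal(dim(split), c(4L, 4L))
  hd <- identify_header(mk_raw(split), lex$fields)
  merged <- merge_repeated_columns(split[-1, , drop = FALSE], hd$map,
                                   split[1, ])
  expect_true(merged$merged)
  expect_equal(ncol(merged$body), 2L)
  # left block rows first, then right block; the padding row is gone
  expect_equal(merged$body[, 1], sprintf("drug%d", 1:5))
  expect_equal(nrow(merged$body), 5L)
  # no repeat -> identity
  id <- merge_repeated_columns(base[-1, , drop = FALSE],
                               c("Drug", "Sensitivity"), base[1, ])
  expect_false(id$merged)
  expect_identical(id$body, base[-1, , drop = FALSE])
})

test_that("merge inverts the side-by-side split on random tables", {
  # oracle equivalence over randomized repeat tables
  set.seed(304)
  for (i in 1:300) {
    n <- sample(3:9, 1)
    base <- random_clean_grid(n)
    split <- corrupt_table(base, "repeated_columns")
    hd <- identify_header(mk_raw(split), lex$fields)
    merged <- merge_repeated_columns(split[-1, , drop = FALSE], hd$map,
                                     split[1, ])
    expect_identical(unname(merged$body), unname(base[-1, , drop = FALSE]))
    expect_identical(unname(merged$raw_header), unname(base[1, ]))
  }
})

test_that("drugs named in text but absent from the body raise the flag", {
  grid <- mk_grid(c("Cephapirin", "Amoxicillin", "Ampicillin"),
                  c(20, 10, 10))
  body <- grid[-1, , drop = FALSE]
  map <- c("Drug", "Sensitivity")
  txt <- "Compounds evaluated: Cephapirin, Amoxicillin, Ampicillin, Penicillin G."
  missing <- detect_missing_rows(body, map, txt, lex)
  expect_equal(missing, "Penicillin G")
  # all present -> nothing flagged
  expect_length(detect_missing_rows(
    body, map, "Covers Cephapirin, Amoxicillin and Ampicillin.", lex), 0)
  # a drug word inside a *test* name is not a missing drug
  expect_length(detect_missing_rows(
    body, map, paste("The Charm Gentamicin test covers Cephapirin,",
                     "Amoxicillin and Ampicillin."), lex), 0)
  expect_length(detect_missing_rows(body, map, "", lex), 0)
})

test_that("unit hints resolve ppb over ppm only when both never co-occur", {
  expect_equal(detect_unit(mk_raw(mk_grid("Penicillin G",
                                          "4", sens_header = "Concentration (ppb)",
                                          drug_header = "Drug")), lex),
               "ppb")
  expect_equal(detect_unit(mk_raw(mk_grid("Penicillin G", "0.004",
                                          sens_header = "Sensitivity ppm",
                                          drug_header = "Drug")), lex),
               "ppm")
  expect_true(is.na(detect_unit(mk_raw(mk_grid("Penicillin G", "4",
                                               sens_header = "Sensitivity")),
                                lex)))
  both <- mk_raw(mk_grid("Penicillin G", "4",
                         sens_header = "Sensitivity ppb",
                         extra_headers = "MRL ppm", extra_cols = "0.1"))
  expect_message(u <- detect_unit(both, lex), "per-column")
  expect_true(is.na(u))
})

test_that("the repair chain is idempotent and conserves rows", {
  grid <- corrupt_table(mk_grid(sprintf("drug%d", 1:6), 1:6), "combined",
                        title_row_text = "Tetracyclines",
                        banner_text = "Quality banner")
  rt <- mk_raw(grid)
  rep1 <- suppressMessages(repair_table(rt, lex))
  expect_setequal(rep1$flags,
                  c("had_banner", "had_title_rows", "had_repeated_columns"))
  expect_equal(rep1$body[, 1], sprintf("drug%d", 1:6))
  # conservation: removals all logged
  removed <- sum(vapply(rep1$repair_log, function(e)
    e$action %in% c("remove_banner", "remove_title_row"), logical(1)))
  expect_true(removed >= 2)
  # run the chain again on its own output: nothing changes
  rt2 <- raw_table(rbind(rep1$raw_header, rep1$body), doc_id = rt$doc_id)
  rep2 <- suppressMessages(repair_table(rt2, lex))
  expect_identical(unname(rep2$body), unname(rep1$body))
  expect_identical(rep2$header, rep1$header)
  expect_length(rep2$repair_log, 0)
})
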