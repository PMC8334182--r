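test_that("upsert covers the full case grid", {
  m0 <- master_sheet(mk_master_row("Penicillin", low = 4))
  # key present, different sensitivity -> update, old value logged
  res <- upsert(m0, mk_incoming("Penicillin", low = 5))
  expect_length(res$report$updated, 1)
  expect_equal(res$report$updated[[1]]$old_low, 4)
  expect_equal(res$master$sens_low_ppb, 5)
  # key present, equal sensitivity -> unchanged
  res2 <- upsert(m0, mk_incoming("Penicillin", low = 4))
  expect_equal(res2$report$unchanged, 1L)
  expect_length(res2$report$updated, 0)
  # key absent -> insert
  res3 <- upsert(m0, mk_incoming("Tylosin", low = 50))
  expect_length(res3$report$inserted, 1)
  expect_equal(nrow(res3$master), 2L)
  # a type difference is a different key (unknown is its own key value)
  res4 <- upsert(m0, mk_incoming("Penicillin", type = "sequential", low = 4))
  expect_length(res4$report$inserted, 1)
})

test_that("upsert is idempotent", {
  m0 <- master_sheet(mk_master_row("Penicillin", low = 4))
  inc <- rbind(mk_incoming("Penicillin", low = 5),
               mk_incoming("Tylosin", low = 50))
  once <- upsert(m0, inc)
  twice <- upsert(once$master, inc)
  expect_length(twice$report$updated, 0)
  expect_length(twice$report$inserted, 0)
  expect_equal(twice$report$unchanged, 2L)
  expect_equal(tibble::as_tibble(twice$master),
               tibble::as_tibble(once$master))
})

test_that("bulk arithmetic: 4 novel + 2 identical onto a 10-row master", {
  drugs10 <- c("Penicillin", "Tylosin", "Neomycin", "Gentamicin",
               "Cephapirin", "Ceftiofur", "Amoxicillin", "Ampicillin",
               "Cloxacillin", "Erythromycin")
  m0 <- master_sheet(do.call(rbind, lapply(seq_along(drugs10), function(i)
    mk_master_row(drugs10[i], low = i))))
  novel <- c("Tetracycline", "Sulfamethazine", "Pirlimycin", "Kanamycin")
  inc <- rbind(
    do.call(rbind, lapply(seq_along(novel), function(i)
      mk_incoming(novel[i], low = 100 + i))),
    mk_incoming("Penicillin", low = 1),
    mk_incoming("Tylosin", low = 2))
  res <- upsert(m0, inc)
  expect_equal(nrow(res$master), 14L)
  expect_equal(res$report$unchanged, 2L)
  expect_length(res$report$inserted, 4)
  expect_length(res$report$updated, 0)
})

test_that("same-run duplicates: later document wins, conflict logged", {
  m0 <- master_sheet()
  inc <- rbind(mk_incoming("Penicillin", low = 4, year = 2019L, month = 5L),
               mk_incoming("Penicillin", low = 6, year = 2020L, month = 1L))
  res <- upsert(m0, inc)
  expect_length(res$report$conflicts, 1)
  expect_equal(res$master$sens_low_ppb, 6)
  expect_equal(nrow(res$master), 1L)
  # date tie -> still resolved deterministically but flagged for review
  inc2 <- rbind(mk_incoming("Tylosin", low = 1, year = 2020L, month = 1L),
                mk_incoming("Tylosin", low = 2, year = 2020L, month = 1L))
  res2 <- upsert(m0, inc2)
  expect_true(res2$report$conflicts[[1]]$needs_review)
})

test_that("non-canonical incoming names are rejected as pipeline bugs", {
  m0 <- master_sheet()
  bad <- mk_incoming("NotADrug")
  expect_error(upsert(m0, bad, lexicon = lex),
               class = "assayharvest_canonical_error")
})

test_that("key uniqueness and monotone growth under random upserts", {
  set.seed(306)
  drugs <- names(lex$synonyms$drug$rows)
  tests <- names(lex$synonyms$test$rows)[1:10]
  m <- master_sheet()
  # oracle: a plain environment keyed the same way
  oracle <- new.env(parent = emptyenv())
  for (step in 1:60) {
    n_in <- sample(1:8, 1)
    inc <- do.call(rbind, lapply(seq_len(n_in), function(j)
      mk_incoming(sample(drugs, 1), test = sample(tests, 1),
                  low = sample(c(4, 5, 50), 1),
                  year = 2020L, month = sample(1:12, 1))))
    prev_n <- nrow(m)
    res <- upsert(m, inc)
    m <- res$master
    keys <- assayharvest:::record_key(m)
    expect_false(anyDuplicated(keys) > 0)
    expect_gte(nrow(m), prev_n)
    # conservation of incoming records across report buckets
    expect_equal(nrow(inc),
                 length(res$report$updated) + length(res$report$inserted) +
                   res$report$unchanged + res$report$suppressed)
    for (k in unique(assayharvest:::record_key(inc))) assign(k, TRUE, oracle)
    expect_equal(nrow(m), length(ls(oracle)))
  }
})

test_that("tolerance join overrides, preserves, and flags", {
  m0 <- master_sheet(rbind(
    mk_master_row("Penicillin", low = 4),
    mk_master_row("Gentamicin", test = "Charm Gentamicin", low = 50)))
  m0$tolerance_ppb[2] <- 30  # came from the source table
  jt <- join_tolerance(m0, c(Penicillin = 5), lexicon = lex)
  expect_equal(jt$master$tolerance_ppb,
               c(5, 30))  # join wins where present, else preserved
  expect_equal(nrow(jt$flagged), 1L)
  expect_equal(jt$flagged$flag, "sensitivity exceeds tolerance")
  expect_warning(join_tolerance(m0, c(Unknowndrugname = 1), lexicon = lex),
                 "non-canonical")
})

test_that("CSV export is byte-stable, ordered, and round-trips", {
  m <- master_sheet(rbind(
    mk_master_row("Tylosin", test = "Veratox for Tylosin", low = 50),
    mk_master_row("Penicillin", low = 4, high = 6, qualifier = "none")))
  p1 <- tempfile(fileext = ".csv"); p2 <- tempfile(fileext = ".csv")
  export_master(m, p1)
  export_master(m, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  got <- read_master(p1)
  expect_equal(tibble::as_tibble(got)[order(got$drug), ],
               tibble::as_tibble(m)[order(m$drug), ])
  # export of an import is byte-identical too
  p3 <- tempfile(fileext = ".csv")
  export_master(got, p3)
  expect_identical(readLines(p1), readLines(p3))
  # empty master -> header-only file
  p4 <- tempfile(fileext = ".csv")
  export_master(master_sheet(), p4)
  expect_length(readLines(p4), 1L)
  # xlsx is not written
  expect_error(export_master(m, tempfile(), format = "xlsx"),
               class = "assayharvest_io_error")
})

test_that("a duplicate key is rejected at sheet construction", {
  expect_error(master_sheet(rbind(mk_master_row("Penicillin"),
                                  mk_master_row("Penicillin"))),
               class = "assayharvest_key_error")
})
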