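test_that("whole-word matching honours boundaries including string edges", {
  ens <- lex$ensembles$matrix
  # boundary at string start / inside a sentence
  expect_equal(match_keyword("Urine samples", ens)$match, "Urine")
  expect_equal(match_keyword("milk", ens)$match, "milk")
  # embedded occurrences must not fire: urine in purines, tissue in
  # intertissued
  expect_identical(nrow(match_keyword("purines", ens)), 0L)
  expect_identical(nrow(match_keyword("intertissued", ens)), 0L)
  # alternation: both serum and sera fire in one pass
  hits <- match_keyword("Serum; see Sera note", ens)
  expect_equal(tolower(hits$match), c("serum", "sera"))
  expect_equal(hits$pattern, rep("\\Wserum\\W|\\WSera\\W", 2))
})

test_that("match spans come back in reading order", {
  hits <- match_keyword("tissue then milk then urine", lex$ensembles$matrix)
  expect_equal(tolower(hits$match), c("tissue", "milk", "urine"))
  expect_true(all(diff(hits$start) > 0))
})

test_that("ensembles validate at construction; metacharacters are literal", {
  expect_error(keyword_ensemble("matrix", character(0)),
               class = "assayharvest_config_error")
  # printed keywords are literal text: regex metacharacters never take
  # effect, so a parenthesis is matched as a character
  ens <- keyword_ensemble("matrix", "\\Wmilk(\\W")
  expect_equal(nrow(match_keyword("see milk( here", ens)), 1L)
  expect_equal(nrow(match_keyword("see milk here", ens)), 0L)
})

test_that("header cells canonicalize to their field names", {
  cases <- list(
    c("Antimicrobial drug", "Drug"),
    c("Active ingredient", "Drug"),
    c("Residues detected", "Drug"),
    c("Detection level", "Sensitivity"),
    c("Concentration for positive ppb", "Sensitivity"),
    c("Test Sensitivity", "Sensitivity"),  # specific alias beats 'Test'
    c("Specimen", "Matrix"),
    c("Action Level", "Tolerance"),
    c("Safe level", "Tolerance"),
    c("MRL ppb", "MRL"),
    c("Test Name", "Test"))
  for (cs in cases) {
    expect_identical(canonicalize_field(cs[1], lex$fields), cs[2],
                     info = cs[1])
  }
  expect_true(is.na(canonicalize_field("Lot number", lex$fields)))
  expect_true(is.na(canonicalize_field("", lex$fields)))
})

test_that("an alias shared by two canonical fields is a dictionary bug", {
  expect_error(
    field_dictionary(list(A = "\\Wfoo\\W", B = c("\\Wbar\\W", "\\Wfoo\\W"))),
    class = "assayharvest_config_error")
})

test_that("entity canonicalization: exact beats containment, longest wins", {
  dr <- lex$synonyms$drug
  expect_equal(canonicalize_entity("Charm Kidney Inhibition Swab",
                                   lex$synonyms$test)$canonical,
               "Charm KIS")
  expect_equal(canonicalize_entity("benzylpenicillin procaine", dr)$canonical,
               "Penicillin")
  expect_equal(canonicalize_entity("benzathine penicillin", dr)$canonical,
               "Penicillin")
  # identity: a canonical name maps to itself
  expect_equal(canonicalize_entity("Penicillin", dr)$canonical, "Penicillin")
  expect_equal(canonicalize_entity("Penicillin", dr)$variant, "Penicillin")
  # containment picks the longest variant (page-title style input)
  hit <- canonicalize_entity("Charm MRL Beta-Lactam and Tetracycline 2-min Test",
                             lex$synonyms$test)
  expect_equal(hit$canonical, "Charm MRL Beta-Lactam and Tetracycline 2-min")
  expect_null(canonicalize_entity("Water", lex$synonyms$matrix))
})

test_that("entity canonicalization is idempotent over the whole vocabulary", {
  for (tbl in lex$synonyms) {
    for (v in unlist(tbl$rows)) {
      once <- canonicalize_entity(v, tbl)$canonical
      expect_identical(canonicalize_entity(once, tbl)$canonical, once)
    }
  }
})

test_that("method words split off drug/test fields from either end", {
  expect_equal(split_method("Penicillin, sequential"),
               list(name = "Penicillin", method = "sequential"))
  expect_equal(split_method("quantitative, Gentamicin"),
               list(name = "Gentamicin", method = "quantitative"))
  expect_equal(split_method("Gentamicin"),
               list(name = "Gentamicin", method = NA_character_))
  # a field that is only a method word: empty name, method set
  expect_equal(split_method("Competitive"),
               list(name = "", method = "competitive"))
  # interior commas in the name survive untouched
  expect_equal(split_method("2,4-D")$name, "2,4-D")
  expect_equal(split_method("2,4-D, sequential"),
               list(name = "2,4-D", method = "sequential"))
})

test_that("PMI matches hand-computed document co-occurrence values", {
  # engineered pair: a and b each in 2 of 8 docs, always together:
  # pmi = log2(8*2/(2*2)) = 2
  docs <- c(rep(list(c("alpha", "beta")), 2), rep(list("filler"), 6))
  res <- pmi_score(docs)
  row <- res[res$word_a == "alpha" & res$word_b == "beta", ]
  expect_equal(row$pmi, 2)
  expect_equal(row$count_ab, 2L)
  # independence-saturated pair: both words in every doc -> pmi = 0
  docs2 <- rep(list(c("x", "y")), 8)
  expect_equal(pmi_score(docs2)$pmi, 0)
  # never co-occurring pair is not emitted
  docs3 <- list(c("p"), c("q"))
  expect_identical(nrow(pmi_score(docs3)), 0L)
  expect_error(pmi_score(list()), class = "assayharvest_config_error")
})

test_that("PMI agrees with a naive counting oracle on random corpora", {
  naive_pmi <- function(docs) {
    docs <- lapply(docs, function(d) unique(tolower(d)))
    vocab <- sort(unique(unlist(docs)))
    n <- length(docs)
    out <- list()
    for (i in seq_along(vocab)) for (j in seq_along(vocab)) {
      if (j <= i) next
      a <- vocab[i]; b <- vocab[j]
      ca <- sum(vapply(docs, function(d) a %in% d, logical(1)))
      cb <- sum(vapply(docs, function(d) b %in% d, logical(1)))
      cab <- sum(vapply(docs, function(d) a %in% d && b %in% d, logical(1)))
      if (cab == 0) next
      out[[length(out) + 1]] <- data.frame(
        word_a = a, word_b = b, count_a = ca, count_b = cb, count_ab = cab,
        pmi = log2(cab * n / (ca * cb)))
    }
    do.call(rbind, out)
  }
  set.seed(401)
  for (rep in 1:5) {
    vocab <- paste0("w", 1:20)
    docs <- lapply(1:12, function(i) sample(vocab, sample(2:8, 1)))
    got <- pmi_score(docs)
    want <- naive_pmi(docs)
    got_sorted <- got[order(got$word_a, got$word_b), ]
    want_sorted <- want[order(want$word_a, want$word_b), ]
    expect_equal(got_sorted$pmi, want_sorted$pmi, tolerance = 1e-12)
    expect_equal(got_sorted$count_ab, want_sorted$count_ab)
  }
})

test_that("dictionary files round-trip through their readers", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("Penicillin,Penicillin G,Benzylpenicillin",
               "\"Charm Sciences, Inc\",Charm"), p)
  tbl <- read_synonym_table(p, "drug")
  expect_equal(names(tbl$rows), c("Penicillin", "Charm Sciences, Inc"))
  expect_true("Penicillin G" %in% tbl$rows$Penicillin)
  # a variant in two rows is rejected
  writeLines(c("A,shared", "B,shared"), p)
  expect_error(read_synonym_table(p, "drug"),
               class = "assayharvest_config_error")
})
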