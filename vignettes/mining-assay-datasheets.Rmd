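---
title: "Mining rapid residue assay datasheets: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining rapid residue assay datasheets: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(assayharvest)
```

## The problem

Commercial farm-side assays for veterinary drug residues (beta-lactams,
tetracyclines, aminoglycosides, sulfonamides and others, in milk, serum,
urine, honey and eggs) publish their specifications in manufacturer PDFs
and web pages, not in any machine-readable registry. A practitioner who
wants to know *which test detects which drug, in which matrix, down to what
concentration, and whether that is at or below the FDA tolerance* must read
dozens of datasheets whose tables are inconsistent in vocabulary and often
structurally damaged by the PDF-to-text conversion itself.

`assayharvest` turns such documents into a single reconciled master
datasheet keyed on (drug, test, matrix, assay type), with sensitivities
normalized to ppb and tolerances joined in from a user-supplied table. The
package is organized as the pipeline runs: harvest, table extraction,
lexicon matching, table repair, record building, reconciliation, plus a
seeded synthetic-corpus generator used for all testing.

## Keyword matching

All recognition is driven by small dictionaries of whole-word patterns in
the `\W...\W` convention: a keyword counts only when not immediately
preceded or followed by a word character, so "urine" never fires inside
"purines" and "tissue" never fires inside "intertissued". Two details are
deliberate:

* A literal `\W` cannot match at the start or end of a string, which would
  reject a header cell that *is* the keyword. Each edge is therefore
  compiled to a lookaround (`(?<!\w)` / `(?!\w)`) that treats string edges
  as boundaries. This is the package's reading of the convention's intent:
  whole-word matching including cell-initial and cell-final words.
* Everything inside the edges is literal text except `.?`, one optional
  character (so `honey.?` also takes "honeys", `Active.?ingredient.?`
  takes "Active ingredient"). Regex metacharacters in dictionary entries
  are never interpreted. All matching is case-insensitive.

Header cells are canonicalized through a field-alias dictionary (e.g.
"Antimicrobial drug" → Drug, "Detection level" → Sensitivity, "Specimen" →
Matrix, "Safe level" → Tolerance). The shipped dictionary contains aliases
that overlap textually — "Test Sensitivity" matches both the `Test` alias
and the more specific `Test.?Sensitivity` alias of `Sensitivity`. Treating
that as a hard ambiguity would reject real headers, so the resolution rule
is: the longest matched span wins; only an exact span tie across two
canonical fields is reported as a dictionary bug.

## Entity canonicalization and synonym discovery

Drug, test, matrix and manufacturer names are resolved against synonym
tables (first column the canonical — most frequent — name, remaining
columns variants). Lookup is exact case-insensitive first, then
longest-variant containment, which is what resolves a page title like
"Charm Kidney Inhibition Swab Test" to the canonical "Charm KIS". The
shipped tables carry the controlled vocabularies of this domain (~90 test
names, 56 drugs, 5 matrices, 7 manufacturers); all are user-overridable
CSV files.

To *propose* new synonym rows, `pmi_score()` ranks word pairs by pointwise
mutual information over document-level co-occurrence counts
(`pmi = log2(count_ab * n_docs / (count_a * count_b))`, the PMI-IR
convention of counting a word once per document). No published threshold
exists for accepting a pair as a synonym, so candidates are emitted for
human review and never merged automatically.

## Table repair

Four structural pathologies recur in extracted tables, and the repair
chain fixes them in a fixed order — banner removal, header identification,
repeated-column merging, title-row removal, then missing-row detection —
chosen so that composed pathologies (a titled table that is also split
side-by-side) unwind correctly:

* **Banner headlines** above the header row are dropped; the header is the
  first row maximizing the number of cells that canonicalize to a field.
* **Repeated column groups** (the canonical header sequence is one block
  repeated k ≥ 2 times) are stacked vertically, left block first. Exact
  block equality is required: looser matching risks merging genuinely
  distinct columns.
* **Drug-class title rows** ("Tetracyclines" spanning the table) are
  removed by the rule that a data row always carries a positive numeric
  token and a title row never does. "Positive number" is read broadly
  (decimals, thousands separators, comparator prefixes, percentages,
  parenthesized values) — the broadest reading that keeps data rows safe.
  The rule is applied only below the header (and banner removal only
  above), because the header row itself contains no numbers and must
  survive.
* **Missing final rows**: extraction sometimes silently drops the last
  table row while the document text still names the drug. Any drug
  mentioned in the text (outside of test/manufacturer names — the
  "Gentamicin" inside "Charm Gentamicin" names the assay, not a tested
  drug) but absent from the body raises `missing_row_suspected` and is
  listed in the repair log. Rows are never synthesized: recovery is a
  human decision.

Every removal is logged, so input rows always equal surviving rows plus
logged removals, and running the chain on its own output changes nothing.

## Records and reconciliation

A record is one (drug, test, matrix, type, sensitivity) fact.
Sensitivities accept points, ranges ("4–6", "4 to 6") and comparator
prefixes (≤, <, >); units resolve in-cell token → column header → table →
default ppb, and ppm is converted ×1000 so stored values are always ppb.
The default unit is ppb because the sensitivity vocabulary of this domain
is ppb-denominated. The qualifier enum has no plain "above", so ">" maps
to `at_or_above`.

`upsert()` implements the update semantics: same key and same sensitivity
is a no-op; same key and a different sensitivity replaces the value (old
value logged); a new key appends a row. "unknown" assay type participates
in the key as its own value so untyped rows never collide with typed ones.
Sensitivity equality is exact on (low, high, qualifier) with 1e-9 ppb
slack — these are catalog numbers, not measurements. Duplicate keys within
one run are conflicts; the later document (year, month) wins, a date tie
is flagged for review. The animal field is recorded but deliberately kept
out of the match key; documents rarely state it and including it would
split otherwise-identical rows.

Tolerances are joined from a user-supplied table keyed by canonical drug
name (they are curated from federal regulations, not mined); a record
whose sensitivity floor exceeds its tolerance is flagged, since such a
test cannot verify compliance at the tolerance. Export is CSV only —
deterministic, key-ordered, byte-stable; no xlsx writer is part of this
package.

## The synthetic corpus

`generate_corpus()` emulates the study conditions end-to-end with no
network access: a `<year>/<month>/` tree of HTML documents and JSON
page-grid documents (the package's plain-text stand-in format for PDFs,
read through the same pluggable `GridExtractor` contract a real PDF engine
would implement), filenames carrying all eight case variants of the "mrk"
marker plus decoy filenames, and a ground-truth CSV. The reference
conditions are 50 documents in proportion 40 : 15 : 15 : 15 : 15 : 15
(clean, missing-row, multi-title, repeated-columns, combined, irrelevant —
normalized to sum to one), 5–8 drugs per document drawn from the real
controlled vocabulary, sensitivities 5–150 ppb, and an 80/20 ppb/ppm unit
mix; this yields roughly 280 truth records per corpus. Matrices are drawn
from the four whose keywords the matrix ensemble recognizes in body text
(Milk, Serum, Urine, Honey); Egg remains in the vocabulary but egg
documents would need an explicit Matrix column, which the generator does
not emit. Test names containing a matrix word are likewise excluded from
the pool so a name never overrides the document's own matrix.

What the generator does *not* emulate — and hence what green tests do not
prove about real documents: OCR noise, cell-boundary detection errors
inside PDF geometry, multi-page tables, merged/spanning cells, and
vocabulary outside the shipped dictionaries. The pathologies it does
emulate are exactly the four structural ones the repair chain targets,
plus irrelevant documents and decoy filenames.

## Numerical and degenerate-input choices

* Tables with no canonicalizable header row are quarantined, not guessed.
* Rows with an empty or unknown drug, an unparseable sensitivity, or no
  resolvable test/matrix are skipped and logged; a table yielding zero
  records is counted as "no relevant fields".
* `detect_unit()` withholds the table-level hint when both ppb and ppm
  appear; units then resolve per column.
* All randomness lives in the fixture generator and is seed-controlled
  (the generator also restores the caller's RNG state); the mining
  pipeline itself is deterministic, and rerunning it over unchanged inputs
  leaves the master untouched.

## Worked example

```{r example, eval = FALSE}
work <- tempfile()
corpus <- generate_corpus(fixture_spec(seed = 7, n_documents = 12), work)
res <- run_pipeline(pipeline_config(corpus$root, file.path(work, "out")))
res$report
head(res$master)
```

The report counts documents, tables found/relevant/parsed, records,
inserts, updates and flagged documents; `master.csv`, `records.csv`,
`manifest.csv` and `report.json` are written under the output directory.
The same quantities, recomputed from scratch at the reference conditions,
are what `scripts/acceptance.R` writes.

## Known limitations

Scanned (image-only) PDFs are out of scope; real PDF table detection must
be supplied as a `GridExtractor` adapter; multi-matrix documents take the
first matrix in reading order (alternatives are logged); and synonym
discovery proposes but never applies merges.
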