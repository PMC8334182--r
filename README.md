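# assayharvest

Mining commercial rapid drug-residue assay datasheets from HTML and PDF
documents into one reconciled master table.

## The problem

Farm-side rapid assays (SNAP, Charm, BetaStar, Delvotest, Veratox, ...)
screen milk, serum, urine, honey and eggs for veterinary drug residues.
Their specifications — which drug a test detects, in which matrix, at what
sensitivity — live in manufacturer PDFs and web pages with inconsistent
vocabulary and tables that extraction routinely damages: banner headlines,
drug-class title rows in mid-table, side-by-side repeated column groups,
and silently dropped final rows. Veterinarians deciding whether a treated
animal's products can enter the food supply need those numbers next to the
FDA tolerance for each drug, in one searchable sheet.

`assayharvest` is that pipeline:

1. **harvest** — walk a `year/month` document listing, keep files whose
   name contains "mrk" in any casing, store with content hashing so
   changed documents are re-extracted;
2. **extract** — HTML tables via xml2; PDF-kind documents through a
   pluggable `GridExtractor` contract (a JSON page-grid reader ships with
   the package); document context (matrix, test name, assay type) from
   body text, page title and URL;
3. **match** — whole-word keyword ensembles compiled boundary-safe (the
   keyword "urine" never fires inside "purines"), a field-alias dictionary
   (`"Antimicrobial drug"` → Drug, `"Detection level"` → Sensitivity),
   and synonym tables mapping variant names to canonical ones
   (`"Charm Kidney Inhibition Swab"` → `"Charm KIS"`), plus PMI-based
   scoring of new synonym candidates;
4. **repair** — classify tables as relevant, then fix the four structural
   pathologies, logging every removal and flagging suspected missing rows
   (`missing_row_suspected`) for human review;
5. **build** — one record per table row: drug, test, matrix, assay type,
   sensitivity normalized to ppb (1 ppm = 1000 ppb), optional MRL and
   tolerance columns captured;
6. **reconcile** — upsert into the master sheet keyed on
   (drug, test, matrix, type): equal sensitivity is a no-op, a changed
   sensitivity updates the row and logs the old value, a new key appends;
   tolerances join from a user-supplied table and records whose
   sensitivity floor exceeds the tolerance are flagged.

A seeded synthetic-corpus generator reproduces all of the above conditions
offline, with ground truth, and is what every test runs against.

## Worked example

```r
library(assayharvest)

work <- tempfile()
corpus <- generate_corpus(fixture_spec(seed = 7, n_documents = 12), work)
res <- run_pipeline(pipeline_config(corpus$root, file.path(work, "out")))
str(res$report)
#> List of 12
#>  $ documents       : int 12
#>  $ tables_found    : int 12
#>  $ tables_relevant : int 11
#>  $ tables_parsed   : int 11
#>  $ records         : int 65
#>  $ inserts         : int 65
#>  $ updates         : int 0
#>  $ unchanged       : int 0
#>  $ conflicts       : int 0
#>  $ quarantined     : int 0
#>  $ missing_row_docs: chr [1:2] "2018-03-MRk-beta-star-4d.html" ...
#>  $ tolerance_flags : int 0
```

Twelve generated documents: one is a navigation page (12 tables found, 11
relevant), two had their final row dropped by the simulated extractor and
are flagged in `missing_row_docs`; the 65 parsed records were all inserted
into an empty master. `res$master` is the reconciled sheet:

```r
print(res$master, n = 4)
#> # A tibble: 65 × 13
#>   drug        test   matrix assay_type  sens_low_ppb sens_high_ppb qualifier
#> 1 Sulfathiaz… Charm… Urine  competitive          100           100 none
#> 2 Erythromyc… Charm… Urine  competitive           10            10 none
#> 3 Sulfameraz… Charm… Urine  competitive           90            90 none
#> 4 Flunixin    Charm… Urine  competitive           40            40 none
```

Sensitivities are ppb; a 0.05-ppm cell in a source table arrives here as
50. Running the same pipeline again reports `inserts: 0, updates: 0` —
reconciliation is idempotent on unchanged inputs. A command-line wrapper
is installed as `exec/assayharvest` (`run`, `fixtures`, `report`
subcommands).

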