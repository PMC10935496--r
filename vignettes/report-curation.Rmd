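---
title: "Curating OCR'd pathology reports: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating OCR'd pathology reports: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(pathreportr)
```

## The problem

Public archives such as The Cancer Genome Atlas (TCGA) hold thousands of
scanned pathology report PDFs. Layout-aware OCR engines can turn these
scans into structured block output — pages, lines, words with bounding
boxes, tables, and checkbox-like "selection elements" — but the raw text
is contaminated with archive-specific artifacts: placeholder forms for
missing reports, diagnosis-discrepancy forms, multiple-choice (synoptic)
form pages whose selected options OCR cannot see, quality-control (QC)
tables stamped onto the scans, handwritten annotations added during
archival QC, and clinic-specific headers and footers. None of these
belong in a machine-readable diagnostic text corpus.

`pathreportr` implements the curation pipeline that removes each artifact
class in turn, assembles one labeled text record per patient, and
benchmarks the result with a one-vs-rest classification harness. The
package consumes Textract-dialect block JSON; it never calls an OCR
engine itself.

## Pipeline stages and their rules

1. **Case selection** (`select_cases()`). Patient-level exclusions from
   the biospecimen and outcomes metadata, applied in a fixed order: no
   pathology report UUID, multiple distinct report UUIDs, no
   primary-tumor sample, no survival data. A patient matching several
   rules is recorded under the first — this affects only the audit
   breakdown, never the kept set. Sample types are compared by exact
   case-insensitive equality to `"primary tumor"` after trimming, so
   variant strings containing the phrase are not accidentally retained.
2. **Report screening** (`screen_corpus()`). A report is excluded when
   the missing-pathology or diagnosis-discrepancy form phrase
   fuzzy-matches any page's concatenated text (allowance 2 edits —
   the phrases are long and OCR noise is common), or when its id is on
   an explicit poor-scan exclusion list. No computable rule exists for
   "poor scan quality", so the package deliberately takes a list rather
   than guessing; a mean-word-confidence advisory flag (floor 50) aids
   triage but never removes anything.
3. **Form detection** (`detect_forms()`). Two-stage funnel: a structural
   screen (tables per report, selection elements per report, mean and
   max selection elements per page — a report is a candidate when *any*
   statistic exceeds its threshold) followed by a disease-specific fuzzy
   keyword screen counting *distinct* matched keywords. Form pages are
   those with at least `min_sel` selection elements or any keyword hit;
   a report is dropped whole only when every page qualifies. Every
   automatic non-KEEP verdict carries `needs_review = TRUE`: the filters
   enrich for forms but are not perfectly specific, so final removal
   goes through a review roster (`apply_review_roster()`).
4. **QC-table removal** (`remove_qc_tables()`). Section-header keywords
   are fuzzy-matched per line; each hit contributes the line's box grown
   by that header's configured offsets; the expanded boxes merge into a
   "max bounding box". A single matched keyword suffices — header
   vocabulary is distinct from body text. Lines whose overlap fraction
   with the box reaches the threshold are excised.
5. **Line cleaning and assembly** (`clean_document()`,
   `build_corpus()`). Lines made entirely of handwritten words are
   removed (mixed lines survive; word-less lines are untouched), then
   lines matching any removal regex (search semantics,
   case-insensitive). Surviving lines join with `". "` within a page and
   pages join with a single space; reports with five or fewer surviving
   lines are flagged, never dropped — such outliers proved to carry
   real diagnostic content. Every stage logs
   `items_in - items_removed = items_out`, enforced by the `audit_log()`
   constructor.

## Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| fuzzy allowance | `ceiling(0.15 * nchar(phrase))` | edits | mis-translation frequency grows with phrase length; override per keyword |
| screening-phrase allowance | 2 | edits | long fixed phrases, tolerant of OCR glyph errors |
| overlap threshold | 0.25 | fraction of line area | calibrated floor: between 0.35 and 0.25 no clinically relevant line is captured, below 0.25 some are; the boundary is inclusive |
| large-box review cap | 0.6 | fraction of page area | outsized merged boxes suggest body text matched a header; review, never auto-remove |
| structural thresholds | 3 / 10 / 4 / 8 | counts | deliberately arbitrary starting points; the original values were empirical and unpublished |
| form page rule `min_sel` | 5 | selection elements | below typical form density, above stray checkbox noise |
| short-report flag | 5 | lines | the reviewed outlier ceiling |
| truncation | 512 | whitespace tokens | input cap of BERT-family clinical models |

Overlap is normalized by the **line's** area, not the table's: that puts
the statistic in [0, 1] and matches the scale on which the 0.25/0.35
thresholds are expressed.

## Fuzzy matching

The matcher is case-folded Levenshtein distance in semi-global
(substring) form: the keyword must align to a contiguous substring with
free endpoints, computed by dynamic programming (in C++, since it runs
over every line of every report). `fuzzy_find()` reports all accepted
matches; overlapping candidates resolve by discarding any candidate
overlapped by a strictly lower-distance one, then greedily keeping the
leftmost (ties: lower distance, then shorter span). At allowance 0 this
is exactly non-overlapping substring search, a property the tests verify
against a naive scan; match distances are verified against
`utils::adist(partial = TRUE)` as an independent oracle.

## What the synthetic generator emulates — and what it does not

`generate_report()` plants every artifact class with recorded ground
truth: a QC table whose nine section headers sit at consistent relative
positions inside a known box (three columns by three rows, value lines
beneath each header), header typos as character substitutions capped at
`max_typo_edits`, all-handwriting lines, clinic headers matching the
default removal regexes, form pages dense in selection elements, and the
two screening phrases. Geometry is valid and non-overlapping by
construction; body and table regions are vertically separated. The
generator's nine header keywords are its own: the header list used for
the real archive lives in unpublished supplementary material, and all
detection code is list-agnostic by design.

Defaults follow the published study conditions where those are stated:
the case-table generator plants the printed category counts (82
multi-report, 399 non-primary, 72 lacking survival among 11,010
patients), the screening generator the printed 381/212/14 removals among
10,457 reports, and the QC validation analog uses 50 reports, mirroring
the prototype set size. Where no value is stated the defaults are one-off
realistic choices: 1–3 pages and 4–8 body lines per page (most scanned
reports are short), a 0.5 QC-table plant rate so both outcomes are well
represented, typo rate 0.3 with at most 2 substitutions (within the
per-header allowance of 2).

Real OCR output is messier in ways the generator does not model:
continuous confidence degradation, skewed or rotated insertions (boxes
here are axis-aligned, as in the source dialect), overlapping geometry,
tokenization errors beyond per-character substitution, and class
vocabularies that overlap heavily across cancer types. Passing tests
therefore demonstrate that the *rules are implemented correctly*, not
that the thresholds transfer to any particular real corpus — thresholds
and keyword sets are configuration for exactly that reason.

Per-class vocabularies are disjoint by default, which forces perfect
separability: the bundled term-frequency baseline must reach test AU-ROC
1.0, and the harness test asserts exactly that. This is a correctness
check of the harness, not a performance claim.

## Evaluation protocol

`run_ovr_experiment()` reproduces the one-vs-rest protocol: a stratified
train/validation/test split (largest-remainder allocation, so every
class's count in every split is within one of exact proportion; the
split is a function of the seed and record ids, not input order), one
binary task per class, softmax on raw two-class scores (overflow-safe),
AU-ROC in Mann–Whitney form with ties at 1/2, AU-PRC by step
interpolation, and best-model selection by validation AU-ROC with ties
to the lowest seed. Cross-seed uncertainty is a Student-t interval,
a convention chosen here since none is published. The transformer that
motivated the protocol stays behind the scorer contract
(`fit`/`score`); the bundled `tf_linear_scorer()` is a sparse
term-frequency ridge logistic fit, deterministic and CPU-friendly. Split
fractions default to 0.8/0.1/0.1 (the published split is not printed;
this is the field's common choice and is configurable).

## Numerical and degenerate-input choices

* Box invariants tolerate `1e-6` overshoot of the unit page for upstream
  rounding; word-in-line containment uses the same tolerance.
* Zero-area line boxes cannot be scored for overlap; they are kept and
  counted rather than silently removed.
* Words lacking a text-type annotation default to `PRINTED`: absence of
  annotation must never delete text.
* Duplicate case rows collapse with a warning; duplicate report ids in a
  corpus are a hard error (one report per patient is a pipeline
  invariant).
* Line texts equal the space-join of their word texts whenever words are
  modeled, enforced by `validate_ocr_document()`.
* Assembly never deduplicates a line's own trailing period against the
  `". "` delimiter — bit-exact, documented behavior.

## Problem sizes used by the test suite

The suite regenerates everything it needs: the full 11,010-patient case
table and the full 10,457-report screening corpus (their arithmetic is
the point), 50 reports for the detection-concordance analog, and 10–100
documents or random geometries per property suite. The whole suite runs
in a few minutes on one CPU. The published corpus-scale figures (9,523
final reports, 23,909 pages, 842,134 lines) and the 0.992 mean AU-ROC
require the real archive and GPU fine-tuning and are out of scope here;
the reference tables shipped in `inst/extdata` carry the published
per-type counts and demographics for consistency checks and realistic
synthetic class profiles.

## Known limitations

* Poor-scan exclusion is list-driven; no image-quality judgment is made.
* Only the colon form-keyword set is complete; liver ships as a
  two-keyword stub and other disease sets must be user-supplied.
* The bundled cleaning regexes are ~20 representative patterns, not a
  complete clinic-header inventory.
* One QC table per page is assumed; disjoint header clusters merge into
  a single (flagged) box.
* Spelling correction, punctuation normalization, and uncasing are
  deliberately out of scope.
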