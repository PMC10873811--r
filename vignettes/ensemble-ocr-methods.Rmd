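---
title: "Ensemble OCR consensus for herbarium labels: models and methods"
author: "herbocr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble OCR consensus for herbarium labels: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbocr)
```

## The problem

Millions of imaged herbarium sheets carry typewritten labels whose content —
taxon, locality, collector, date — exists only as pixels. Off-the-shelf OCR
engines transcribe such labels erratically: aged paper, historic typefaces,
stamps and stray marks defeat any single engine/pre-processing combination,
and the combination that works best differs from sheet to sheet. `herbocr`
implements the ensemble answer to this instability: run *several*
pre-processing variants through *several* engines, treat each resulting text
as one noisy read of the same underlying sequence, and merge the reads with
the machinery molecular biology uses for homologous sequences — multiple
sequence alignment and consensus calling.

The package covers the full surrounding workflow: reconciling the
crowdsourced bounding-box annotations that train and validate label
detectors, the image pre-processing chain, pluggable OCR engine adapters, the
alignment/consensus core, lexicon-based post-correction, and an evaluation
harness that sweeps every pipeline configuration against a verbatim gold
standard. A synthetic label renderer plus a seeded noisy-OCR simulator make
every stage testable with no OCR engine installed.

## Bounding-box reconciliation

Crowdsourcing platforms collect three independent outlines per label
(the usual retirement limit). `reconcileAnnotations()` merges them:

* **Outlier trimming.** The overlap metric is the IoU (intersection over
  union), the same metric used to score detector predictions. While any
  outline's mean IoU against the current others falls below the threshold
  (default 0.5), the worst outline is removed and the means recomputed.
  Trimming is iterative rather than a single simultaneous pass for a
  concrete reason: with three outlines of which one is garbage (IoU ≈ 0
  to the others) and two merely agree well (IoU ≈ 0.9), a simultaneous
  rule would see every mean below 0.5 and discard all three, whereas
  worst-first trimming removes the garbage outline and then finds the
  survivors consistent. If trimming cannot leave two mutually consistent
  outlines the label errors out to human review.
* **Averaging.** Survivors are averaged corner-wise — the arithmetic mean of
  each of the four box coordinates — the simplest estimator consistent with
  averaging outlines.
* **Typing.** The label type (typewritten / handwritten / both / barcode /
  other) is the *strict* majority among survivors; 2-of-3 suffices, but
  all-distinct votes return `unresolved` rather than a guess, because the
  workflow routes ambiguity to humans.

Detector output is scored by `scorePredictions()`: greedy one-to-one matching
in descending IoU (deterministic, adequate for the ≤ ~10 labels a sheet
carries), with unmatched predictions reported as phantom labels and unmatched
truths as misses. Coordinates are 0-based pixels, boxes inclusive-min /
exclusive-max for area arithmetic; click containment in
`cleanCorrectionClicks()` is boundary-inclusive, and a click inside nested
boxes is assigned to the smallest.

## The pre-processing variants

Four cumulative variants feed the ensemble, each a superset of the last:

| variant | steps |
|---|---|
| `V1_none` | the unmodified label image |
| `V2_deskew` | slight Gaussian blur → isotropic rescale → orient upright → deskew |
| `V3_binarize` | all of V2, then Sauvola binarization |
| `V4_denoise` | all of V3, then despeckle + hole filling |

Tunable parameters, all in `preprocParams()` with these defaults: blur sigma
0.5 px (just enough to suppress scanner noise without eroding glyphs);
rescale target 4096 px on the long side (a size OCR engines handle well);
Sauvola window 31 px, `k = 0.2`, `R = 128` (the customary document-image
values; the threshold is `T = m(1 + k(s/R − 1))` with windowed mean `m` and
standard deviation `s`, windows clamped at borders, a pixel being ink iff
strictly below `T`); speck and hole limits 4 px; deskew search ±10° in 0.1°
steps. None of these is sacred; they are exposed because real collections
differ.

Two design points deserve notes:

* **Orientation.** "Right side up" is decided by a projection-profile score:
  the variance of the row-sum profile separates horizontal from sideways
  text (text lines are bands), and a baseline-asymmetry statistic separates
  upright from upside-down — upright Latin text piles ink into the x-height
  band just above the baseline with a long sparse tail up into the
  ascender/capital zone, so the per-line profile skews toward the top.
  All-capital text is nearly symmetric under 180° at the profile level and
  is flagged low-confidence, as are blank images (rotation 0). An
  engine-native orientation detector can be layered on through the adapter
  options where an engine is installed.
* **Deskew.** The estimate maximizes the variance of the sheared
  row-projection profile over the angle grid (the classic document skew
  estimator); ties prefer the smallest magnitude. The correction is applied
  as a vertical shear (per-column shift), which is the exact inverse of the
  synthetic renderer's skew model and equal to a rotation to first order in
  the ±10° regime; it cannot resample or blur the image.

`despeckleFill()` uses 8-connectivity for foreground and 4-connectivity for
background — the standard dual pairing that prevents a diagonal pixel chain
from simultaneously connecting ink and enclosing background.

## Engines and the simulator

Engines hide behind the `EngineAdapter` contract (`isAvailable()`,
`transcribe()`). Adapters for the Tesseract binary and the Python EasyOCR
package ship with the package; both were pinned upstream at specific versions
(4.1.1 and 1.6.2), and other installed versions are accepted with a warning
recorded in provenance. An unavailable engine *errors*; it never returns
empty text, so a missing binary cannot impersonate a blank label.

Because real engine output is environment-dependent, tests and experiments
use `SimulatedEngine`: `renderLabel()` rasterizes text with a small built-in
bitmap typeface (deterministic across machines — system fonts are not), with
known skew and speckle density returned as ground truth, and `simulateOCR()`
corrupts the truth with per-character substitution / insertion / deletion
rates, preferring substitutions inside visual confusion classes (l/1/I/|,
O/0, S/5, Z/2, B/8, ...). The simulator is seeded and bit-reproducible, and
it records its applied event counts so tests can compare edit distances
against the number of edits actually made.

What the generator emulates — and what it does not. It reproduces the
*statistical* structure the consensus algorithm exploits: several
conditionally independent noisy reads of one underlying text with
shape-confusable substitutions. It does not reproduce correlated engine
failure modes (two engines misreading the same degraded glyph the same way),
layout errors (column reflow, merged lines), or handwriting. Passing the
recovery experiments therefore demonstrates the merging machinery under
realistic error *rates*, not end-to-end accuracy on real herbarium imagery,
which depends on the installed engines.

The synthetic gold generator (`syntheticGoldSet()`) assembles label-like
texts — heading, binomial, locality, habitat, collector/date lines — from a
built-in vocabulary, with target lengths drawn from 200–600 characters, the
length range of typical typewritten labels. Stream error rates in the
recovery experiments are drawn uniformly from 5–10% per character, split
70/15/15 between substitutions, insertions and deletions — mid-range for
document OCR on degraded material, and deliberately hard enough that single
streams carry dozens of errors per label.

## The consensus core

Given up to eight streams per label, the pipeline is:

1. **Pre-alignment substitutions** (`preSubstitutions()`): engines commonly
   insert whitespace before punctuation and duplicate spaces; an ordered,
   idempotent rule list repairs these per stream.
2. **Outlier pruning** (`pruneOutliers()`): the two globally closest streams
   are the anchor pair; any stream whose Levenshtein distance to that pair
   exceeds the cutoff (default 128) is dropped. The published rule — a
   distance "from the two closest sequences" — is ambiguous between this
   anchor-pair reading and a k-nearest-neighbour reading; the anchor-pair
   semantics is chosen because it guarantees a surviving core (never fewer
   than the two anchors, never more than n − 2 removed) while still
   discarding complete OCR failures. With one or two streams nothing is
   pruned.
3. **Progressive MSA** (`buildMSA()`): center-star-style. The seed is the
   stream with minimum summed Levenshtein distance to the others; remaining
   streams join in ascending distance from the seed; each joins by a global
   Gotoh alignment of sequence against profile. Once a gap column exists it
   is never removed. Exact multi-dimensional alignment is exponential in the
   number of streams; progressive alignment of ≤ 8 label-length streams runs
   in milliseconds and is guarded by exhaustive small-instance oracles in
   the tests.
4. **Consensus calling** (`callConsensus()`): per column, plurality vote
   with the gap as a first-class candidate (a winning gap emits nothing);
   ties break toward the seed row's symbol, then lexicographically. The
   fraction of rows supporting each emitted character is returned as
   per-character support.

**Scoring.** In place of PAM/BLOSUM, a visual-similarity matrix: +2 for
identical characters down to −2 for grossly different shapes (a period
against a W), gap open −3, gap extension −0.5 (the first gap symbol of a run
costs the opening penalty; the published convention does not say whether
opening includes the first extension, and this reading is fixed and
documented). Between the fixed endpoints the scores are this package's
shipped defaults, configurable and loadable from a TSV of confusability
classes and class-pair scores: +1 within a confusability class or for case
pairs, 0 for unrelated letters or unrelated digits, −1 for letter–digit and
punctuation–punctuation pairs, −2 across gross categories (anything against
space, punctuation against alphanumerics). The space is an ordinary
alphabet character — word boundaries matter on labels. Matrix files are
validated on load: symmetry, the [−2, 2] range, and the fixed +2 diagonal.

**Numerical choices.** Character-vs-profile-column score is the mean
similarity to the column's non-gap symbols. Alignment ties prefer
match/mismatch over gaps, then a gap in the incoming sequence, making
results order-independent of equal-score alternatives. The profile
alignment restricts its dynamic program to a diagonal band (width
`max(64, 2·Δlength + 32)`) when stream lengths agree within a factor of
two — OCR streams of one label are near-identical, and the band is an
order-of-magnitude speedup; the band always contains the corner-to-corner
path, and `pairwiseAlign()` always runs the full exact DP (that is the form
the brute-force oracle checks). The gap sentinel is the non-printable
U+001F, rejected in any input text. Degenerate inputs: empty strings align
at pure gap cost (two characters against nothing score −3.5); a
single-stream "ensemble" bypasses pruning and alignment entirely.

## Post-processing

`postCleanup()` runs after consensus when a permutation asks for it: ordered
substitution rules (a deliberately small, idempotent starter set — published
substitution lists for this domain are neither extensive nor weighted), a
split-word repair that joins two adjacent fragments when the join is in the
lexicon and neither fragment is, and unique-neighbour spell correction:
an out-of-lexicon token is replaced only when exactly one lexicon term lies
within the correction radius (default edit distance 1). Zero or multiple
candidates mean abstention — the gold standard is verbatim, so hallucinating
a plausible word is worse than leaving an error. Digit-only tokens are
exempt — collection numbers, dates and coordinates are dense on labels and no
lexicon can vouch for them — and so are tokens of at most `maxEdit + 1`
characters, which a within-radius edit could rewrite almost entirely (a
compass "W" must not become a vocabulary "m"). Every change is logged, and `replayChanges()`
reproduces the output from the input and the log exactly.

## Evaluation and the permutation sweep

A pipeline *permutation* is a nonempty subset of the eight
(variant × engine) streams plus the post-processing flag:
(2⁸ − 1) × 2 = 510 configurations, enumerated deterministically by
`enumeratePermutations()`. The error of a transcription against its verbatim
gold label is the character-level Levenshtein distance — the natural choice
given that the gold rubric forbids semantic normalization and Levenshtein is
already the pipeline's distance; the only default normalization is stripping
leading/trailing whitespace (anything stronger is a config switch, off by
default, because the published evaluation does not state one). A
permutation's score is the cumulative error over the gold set;
`sweepPermutations()` ranks all permutations, reusing each stream subset's
consensus for the post-processing on/off pair (cache transparency is
tested), and emits the familiar report layout — one Y/N column per stream,
the post-process flag, total errors — plus provenance (package version,
config and matrix hashes).

Whether "both"-type labels should be OCR'd is not settled upstream; the JSON
export follows the client behaviour of treating only typewritten labels as
OCR-eligible.

## Problem sizes used in the shipped experiments

The test suite validates the alignment core against brute-force oracles
(500 random pairs ≤ 8 characters for the affine-gap optimum, with the
memoized oracle itself validated against true exhaustive enumeration at
≤ 4 characters; 1000 random pairs for the Levenshtein DP), the Sauvola and
connected-component implementations against naive reimplementations on
32×32 and 28×28 fixtures, and deskew against rendered ground truth within
±0.5°. The ensemble-recovery experiment runs 100 seeded replicates of 50
synthetic labels with eight streams each; the acceptance script reruns the
same experiment at 20 replicates and adds a full 510-permutation sweep over
5 labels. These sizes give stable stochastic estimates (binomial standard
error below 5 points on the win fraction) while keeping a laptop run in
minutes.

## Known limitations

* The consensus weighting is uniform across surviving streams; weighting
  streams (or regions) by estimated quality is an obvious next step.
* The progressive MSA is a heuristic; pathological stream sets can yield
  suboptimal joint alignments (the per-stage oracles bound, but do not
  eliminate, this).
* The orientation heuristic cannot orient all-capital labels under 180°
  rotation from the profile alone and says so via its confidence flag.
* The built-in typeface and vocabulary make fixtures deterministic, not
  typographically realistic; engine-specific behaviour (page segmentation,
  language packs) is passed through to the engines untouched.
* No label detector ships: detection is consumed through the box-JSON
  interchange format, and handwriting is out of scope.
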