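# herbocr

Ensemble OCR with visual-similarity consensus for typewritten natural-history
specimen labels.

## The problem

Herbaria have imaged millions of specimen sheets faster than anyone can
transcribe the labels glued to them. Off-the-shelf OCR is unreliable on this
material — aged paper, historic typefaces, stamps and stray marks — and no
single engine or image pre-processing recipe wins across sheets. `herbocr`
implements the ensemble remedy: treat each (pre-processing variant × OCR
engine) combination as one noisy read of the same underlying text, and merge
up to eight reads per label the way molecular biology merges homologous
sequences.

The core is a progressive multiple sequence alignment under a
**visual-similarity substitution matrix** — the OCR analogue of PAM/BLOSUM.
Character pairs score from +2 (identical) down to −2 (grossly different
shapes: a period vs. a W), with +1 inside confusability classes (l/1/I/|,
O/0, S/5, …). Gaps are affine: −3 to open a run, −0.5 per additional gap
character. Before alignment, streams whose Levenshtein distance from the two
closest streams exceeds a cutoff (default 128) are discarded as complete OCR
failures; after alignment, a per-column plurality vote (gap included as a
candidate, ties broken toward the most central stream) yields the consensus,
and an optional post-processing pass applies substitution rules, split-word
repair and abstaining unique-neighbour spell correction against a lexicon.

Around the core, the package provides:

* **boxes** — reconciliation of crowdsourced label outlines (IoU, iterative
  outlier trimming, corner-wise averaging, majority-rule typing), correction-
  click cleaning, detector scoring (mean IoU, phantoms, misses), label JSON.
* **preproc** — the four cumulative image variants feeding the ensemble:
  unmodified; blur/rescale/orient/deskew; + Sauvola binarization;
  + despeckle/hole-fill. Provenance is recorded on every image.
* **engines** — adapters for Tesseract and EasyOCR (optional, fail loudly
  when missing), plus a deterministic label renderer and seeded noisy-OCR
  simulator so everything is testable without engines.
* **textclean** — lexicon loading and the post-consensus cleanup with a
  replayable change log.
* **pipeline_eval** — enumeration of all (2⁸−1)×2 = 510 pipeline
  permutations, end-to-end permutation runs, verbatim gold-standard
  evaluation (cumulative character-level Levenshtein error) and the ranked
  permutation sweep.

## Worked example

Simulate one label's eight OCR streams at realistic error rates and merge
them:

```r
library(herbocr)

truth   <- syntheticLabelText(220, seed = 42)   # a plausible label text
streams <- simulateStreamSet(truth, seed = 42)  # 8 noisy reads, 5-10% CER
cfg     <- pipelineConfig(lexicon = defaultLexicon())

ct <- runPermutation(streams, permutation(streamCombos(), TRUE), cfg)

vapply(streams, function(s) levenshtein(streamText(s), truth), integer(1))
#> V1_none.easyocr ... V4_denoise.tesseract
#>  21 20 15 16 20 14  6 21
levenshtein(consensusText(ct), truth)
#> 0
```

Each individual stream carries 6–21 character errors on this 241-character
label; the aligned consensus with post-processing reconstructs the truth
exactly. The same objects drive the full sweep: `sweepPermutations()` scores
any set of permutations against a verbatim gold table
(`label_id` / `text` TSV) and returns the ranked report with one Y/N column
per stream, the post-process flag and total errors.

A thin CLI wraps the same functions (`inst/cli/herbocr`): subcommands
`find-labels` (box JSON in/out), `ocr`, `sweep`, `evaluate` and `simulate`.

## Notes

* The similarity matrix, gap penalties, outlier cutoff, substitution rules
  and lexicon are all configurable (`pipelineConfig()`); the similarity
  matrix loads from a TSV of confusability classes
  (`readSimilarityMatrix()`).
* No label detector ships with the package; detector output is consumed via
  the box-JSON interchange format. Handwriting is out of scope.
* See the methods vignette (`vignettes/ensemble-ocr-methods.Rmd`) for the
  models, parameter defaults, numerical choices and known limitations.
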