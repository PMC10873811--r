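#' @include textclean.R render.R
NULL

## Built-in vocabulary for the synthetic label generator. The word stock
## mimics what a typewritten herbarium label carries: a herbarium/flora
## heading, a binomial, locality and habitat phrases, collector and date
## lines. It doubles as the default correction lexicon, the way a field
## lexicon covers real label vocabulary.

.labelVocab <- function() {
  list(
    genera = c("Quercus", "Carex", "Solidago", "Asclepias", "Panicum",
               "Juncus", "Salvia", "Viola", "Trifolium", "Penstemon",
               "Eupatorium", "Aster", "Rubus", "Silene", "Verbena",
               "Helianthus", "Ludwigia", "Polygonum", "Ranunculus", "Smilax"),
    epithets = c("alba", "virginiana", "occidentalis", "canadensis",
                 "angustifolia", "lanceolata", "glabra", "pubescens",
                 "tenuifolia", "cordata", "villosa", "parviflora", "rigida",
                 "serotina", "tomentosa", "repens", "maritima", "palustris"),
    states = c("Texas", "Florida", "Georgia", "Alabama", "Virginia",
               "Tennessee", "Carolina", "Louisiana", "Arkansas",
               "Mississippi"),
    counties = c("Travis", "Alachua", "Fulton", "Mobile", "Fairfax", "Knox",
                 "Wake", "Orleans", "Pulaski", "Hinds", "Leon", "Bexar"),
    surnames = c("Smith", "Jones", "Correll", "Godfrey", "Harper", "Kral",
                 "Duncan", "Radford", "Thieret", "McVaugh"),
    habitat = c("roadside", "meadow", "pine", "woods", "sandy", "soil",
                "moist", "ravine", "bank", "creek", "open", "field", "dry",
                "hillside", "swamp", "margin", "bottomland", "granite",
                "outcrop", "pasture", "thicket", "bluff", "river", "flats"),
    months = c("January", "February", "March", "April", "May", "June",
               "July", "August", "September", "October", "November",
               "December"),
    framework = c("Herbarium", "University", "Flora", "of", "County", "Plants",
                  "Collected", "by", "No", "alt", "elev", "ft", "m", "State",
                  "Herb", "Dept", "Botany", "vicinity", "near", "along", "with",
                  "frequent", "locally", "common", "flowers", "yellow", "white",
                  "purple", "corolla", "in", "fruit", "det"))
}

#' The default correction lexicon
#'
#' All alphabetic vocabulary of the synthetic label generator. For real
#' labels, load institution-specific word lists with
#' \code{\link{loadLexicon}} instead.
#'
#' @param maxEdit correction radius
#' @return a \linkS4class{Lexicon}
#' @export
defaultLexicon <- function(maxEdit = 1L) {
  lexicon(unique(unlist(.labelVocab())), maxEdit)
}

#' Generate one synthetic label text
#'
#' Assembles a plausible typewritten label -- heading, binomial, locality,
#' habitat, collector and date lines -- from the built-in vocabulary until
#' the target character count is reached. Only characters the built-in
#' typeface can draw are used. Deterministic given the seed.
#'
#' @param targetLength approximate text length in characters (the result is
#'   at least this long)
#' @param seed integer seed
#' @return a single string, lines separated by newlines
#' @export
syntheticLabelText <- function(targetLength = 300, seed = 1L) {
  v <- .labelVocab()
  withSeed(seed, {
    pick <- function(x, n = 1) sample(x, n, replace = TRUE)
    lines <- c(
      paste("Flora of", pick(v$states)),
      paste0(pick(v$counties), " County"),
      paste(pick(v$genera), pick(v$epithets)))
    repeat {
      kind <- sample(c("habitat", "locality", "collector"), 1)
      ln <- switch(kind,
        habitat = paste(pick(v$habitat, sample(3:6, 1)), collapse = " "),
        locality = paste(sample(c("near", "along", "vicinity of"), 1),
                         pick(v$habitat), pick(v$habitat),
                         paste0(sample(1:20, 1), " m ",
                                sample(c("N", "S", "E", "W"), 1), " of"),
                         pick(v$counties)),
        collector = paste0("Collected by ", pick(v$surnames), " No. ",
                           sample(100:9999, 1), ", ", sample(1:28, 1), " ",
                           pick(v$months), " 19", sample(30:85, 1)))
      lines <- c(lines, ln)
      if (sum(nchar(lines)) + length(lines) - 1 >= targetLength) break
    }
    paste(lines, collapse = "\n")
  })
}

#' Generate a synthetic gold-standard set
#'
#' @param n number of labels
#' @param seed integer seed
#' @param lengthRange character-count range to draw each label's target
#'   length from
#' @return data.frame with \code{label_id} and \code{text} (the verbatim
#'   ground truth)
#' @export
syntheticGoldSet <- function(n = 50, seed = 1L,
                             lengthRange = c(200, 600)) {
  lens <- withSeed(seed, round(runif(n, lengthRange[1], lengthRange[2])))
  data.frame(
    label_id = sprintf("label%03d", seq_len(n)),
    text = vapply(seq_len(n),
                  function(i) syntheticLabelText(lens[i],
                                                 deriveSeed(seed, "text", i)),
                  character(1)),
    stringsAsFactors = FALSE)
}

#' Stream ids of the eight (variant, engine) combinations
#'
#' Canonical order: V1..V4, each with easyocr before tesseract, matching the
#' permutation table layout.
#' @return character vector of length 8
#' @export
streamCombos <- function() {
  as.vector(t(outer(preprocVariants, c("easyocr", "tesseract"),
                    paste, sep = ".")))
}

#' Simulate the eight OCR streams of one label
#'
#' A fixture for sweeps and recovery experiments: each of the eight
#' (pre-processing variant, engine) combinations gets an independent noisy
#' reading of the truth. Each stream's total per-character error rate is
#' drawn uniformly from \code{errRange} and split 70/15/15 between
#' substitutions, insertions and deletions.
#'
#' @param truth ground-truth label text
#' @param seed integer seed
#' @param errRange total per-character error-rate range
#' @param labelId label identifier recorded on the streams
#' @return named list of eight \linkS4class{OCRStream}s, names =
#'   \code{\link{streamCombos}}
#' @export
simulateStreamSet <- function(truth, seed = 1L, errRange = c(0.05, 0.10),
                              labelId = "label") {
  combos <- streamCombos()
  out <- list()
  for (k in seq_along(combos)) {
    sk <- deriveSeed(seed, "stream", combos[k], labelId)
    rate <- withSeed(sk, runif(1, errRange[1], errRange[2]))
    nm <- noiseModel(subRate = 0.70 * rate, insRate = 0.15 * rate,
                     delRate = 0.15 * rate, seed = sk)
    s <- simulateOCR(truth, nm, seed = deriveSeed(sk, "noise"))
    parts <- strsplit(combos[k], ".", fixed = TRUE)[[1]]
    s@variantId <- parts[1]
    s@engineId <- parts[2]
    s@labelId <- labelId
    out[[combos[k]]] <- s
  }
  out
}
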