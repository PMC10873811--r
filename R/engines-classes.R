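#' @include preproc-classes.R
NULL

#' One engine's transcription of one pre-processed label image
#'
#' The unit the consensus machinery works on: up to eight streams per label
#' (four pre-processing variants times two engines). Engine and variant ids
#' are always recorded so a stream can be mapped onto a pipeline permutation.
#'
#' @slot text the transcription
#' @slot engineId e.g. \code{"tesseract"}, \code{"easyocr"},
#'   \code{"simulated:<name>"}
#' @slot variantId one of \code{preprocVariants} (or \code{"raw"})
#' @slot labelId source label identifier
#' @slot metadata free-form list (the simulator records its applied edit
#'   events here)
#' @export
setClass("OCRStream",
  representation(text = "character", engineId = "character",
                 variantId = "character", labelId = "character",
                 metadata = "list"),
  prototype(metadata = list()),
  validity = function(object) {
    if (length(object@engineId) != 1 || !nzchar(object@engineId))
      return("engineId must be recorded")
    if (length(object@variantId) != 1 || !nzchar(object@variantId))
      return("variantId must be recorded")
    TRUE
  })

#' @param text transcription text
#' @param engineId engine identifier
#' @param variantId pre-processing variant identifier
#' @param labelId label identifier
#' @param metadata optional list
#' @rdname OCRStream-class
#' @export
ocrStream <- function(text, engineId, variantId = "raw", labelId = "label",
                      metadata = list()) {
  new("OCRStream", text = text, engineId = engineId, variantId = variantId,
      labelId = labelId, metadata = metadata)
}

#' @rdname OCRStream-class
#' @param stream an \code{OCRStream}
#' @export
streamText <- function(stream) stream@text

setMethod("show", "OCRStream", function(object) {
  txt <- object@text
  if (nchar(txt) > 50) txt <- paste0(substr(txt, 1, 47), "...")
  cat(sprintf("OCRStream [%s/%s] %s: \"%s\"\n", object@engineId,
              object@variantId, object@labelId, txt))
})

#' Per-character OCR error model for the simulator
#'
#' Substitutions, insertions and deletions are applied independently per
#' character position (insertions between positions); substitutions prefer a
#' visually confusable character when the position's character belongs to a
#' confusion class. Deterministic given the seed.
#'
#' @slot subRate,insRate,delRate per-character probabilities in [0, 1];
#'   \code{subRate + delRate <= 1}
#' @slot confusionClasses list of character vectors of visually confusable
#'   glyphs
#' @slot alphabet characters insertions and unconstrained substitutions draw
#'   from
#' @slot seed integer random seed
#' @export
setClass("NoiseModel",
  representation(subRate = "numeric", insRate = "numeric",
                 delRate = "numeric", confusionClasses = "list",
                 alphabet = "character", seed = "integer"),
  validity = function(object) {
    r <- c(object@subRate, object@insRate, object@delRate)
    if (any(r < 0) || any(r > 1)) return("rates must lie in [0, 1]")
    if (object@subRate + object@delRate > 1)
      return("subRate + delRate must be <= 1 per character")
    TRUE
  })

#' Default visual confusion classes
#'
#' Small published-style table of Latin-script lookalikes used both by the
#' noise simulator and as the +1 classes of the default similarity matrix.
#' @return list of character vectors
#' @export
defaultConfusionClasses <- function() {
  list(c("l", "1", "I", "|"), c("O", "0"), c("S", "5"), c("Z", "2"),
       c("B", "8"), c("m", "n"), c("G", "6"), c("o", "c"))
}

#' @param subRate,insRate,delRate per-character event probabilities
#' @param confusionClasses list of confusable character groups
#' @param alphabet candidate characters for insertions/substitutions
#' @param seed integer seed
#' @rdname NoiseModel-class
#' @export
noiseModel <- function(subRate = 0.05, insRate = 0.01, delRate = 0.01,
                       confusionClasses = defaultConfusionClasses(),
                       alphabet = setdiff(printableChars(), " "),
                       seed = 1L) {
  new("NoiseModel", subRate = subRate, insRate = insRate, delRate = delRate,
      confusionClasses = confusionClasses, alphabet = alphabet,
      seed = as.integer(seed))
}

#' Virtual OCR engine adapter
#'
#' Engines are optional runtime dependencies hidden behind this contract:
#' \code{\link{isAvailable}} probes the environment, \code{\link{transcribe}}
#' runs the engine. An unavailable adapter raises an error -- it never
#' silently returns empty text, so a missing engine can never masquerade as a
#' blank label.
#'
#' @slot engineId identifier recorded on every produced stream
#' @export
setClass("EngineAdapter", representation("VIRTUAL", engineId = "character"))

setMethod("show", "EngineAdapter", function(object) {
  cat(sprintf("<%s engine adapter '%s', %savailable>\n", class(object),
              object@engineId, if (isAvailable(object)) "" else "NOT "))
})
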