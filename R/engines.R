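#' @include engines-classes.R
NULL

#' Simulated OCR engine
#'
#' A test double that "reads" a rendered label by taking the ground-truth
#' text stored in the image metadata and corrupting it with a
#' \linkS4class{NoiseModel}. The effective seed is derived from the model
#' seed, the engine id, the image's variant and the label id, so the eight
#' streams of one label are independent but fully reproducible.
#'
#' @slot model a \linkS4class{NoiseModel}
#' @export
setClass("SimulatedEngine", contains = "EngineAdapter",
         representation(model = "NoiseModel"))

#' @param name short engine name; the engine id becomes
#'   \code{"simulated:<name>"}
#' @param model a \linkS4class{NoiseModel}
#' @rdname SimulatedEngine-class
#' @export
simulatedEngine <- function(name = "sim", model = noiseModel()) {
  new("SimulatedEngine", engineId = paste0("simulated:", name), model = model)
}

setMethod("isAvailable", "SimulatedEngine", function(adapter) TRUE)

setMethod("transcribe", "SimulatedEngine", function(adapter, img, ...) {
  truth <- img@metadata$truthText
  if (is.null(truth))
    stop("SimulatedEngine needs a rendered image carrying truthText metadata")
  m <- adapter@model
  seed <- deriveSeed(m@seed, adapter@engineId, img@variantApplied,
                     img@metadata$labelId %||% "label")
  out <- simulateOCR(truth, m, seed = seed)
  out@engineId <- adapter@engineId
  out@variantId <- img@variantApplied
  out@labelId <- img@metadata$labelId %||% "label"
  out
})

#' Tesseract engine adapter
#'
#' Wraps the \code{tesseract} command-line binary when one is on the PATH.
#' The upstream pipeline was built against Tesseract 4.1.1; any installed
#' version is accepted with a warning. Extra arguments (e.g. \code{"--psm 6"})
#' are passed through.
#'
#' @slot extraArgs character vector of pass-through command-line arguments
#' @export
setClass("TesseractEngine", contains = "EngineAdapter",
         representation(extraArgs = "character"))

#' @param extraArgs pass-through arguments for the binary
#' @rdname TesseractEngine-class
#' @export
tesseractEngine <- function(extraArgs = character()) {
  new("TesseractEngine", engineId = "tesseract", extraArgs = extraArgs)
}

setMethod("isAvailable", "TesseractEngine", function(adapter) {
  nzchar(Sys.which("tesseract"))
})

setMethod("transcribe", "TesseractEngine", function(adapter, img, ...) {
  if (!isAvailable(adapter))
    stop("OCR engine 'tesseract' is not available on this system")
  ver <- tryCatch(system2("tesseract", "--version", stdout = TRUE,
                          stderr = TRUE)[1], error = function(e) "unknown")
  if (!grepl("4\\.1\\.1", ver))
    warning("tesseract version differs from the pinned 4.1.1: ", ver)
  f <- tempfile(fileext = ".png")
  on.exit(unlink(c(f, paste0(f, ".txt"))))
  writeLabelImage(img, f)
  system2("tesseract", c(f, f, adapter@extraArgs), stdout = FALSE,
          stderr = FALSE)
  txt <- paste(readLines(paste0(f, ".txt"), warn = FALSE), collapse = "\n")
  ocrStream(txt, "tesseract", img@variantApplied,
            img@metadata$labelId %||% "label",
            metadata = list(version = ver))
})

#' EasyOCR engine adapter
#'
#' Wraps the Python \code{easyocr} package (pinned upstream at 1.6.2; any
#' importable version is accepted with a warning) through the \code{python}
#' interpreter on the PATH.
#'
#' @slot languages language codes passed to the reader
#' @export
setClass("EasyOCREngine", contains = "EngineAdapter",
         representation(languages = "character"))

#' @param languages language codes, default English
#' @rdname EasyOCREngine-class
#' @export
easyocrEngine <- function(languages = "en") {
  new("EasyOCREngine", engineId = "easyocr", languages = languages)
}

setMethod("isAvailable", "EasyOCREngine", function(adapter) {
  if (!nzchar(Sys.which("python"))) return(FALSE)
  ok <- suppressWarnings(system2("python", c("-c", shQuote("import easyocr")),
                                 stdout = FALSE, stderr = FALSE))
  identical(ok, 0L)
})

setMethod("transcribe", "EasyOCREngine", function(adapter, img, ...) {
  if (!isAvailable(adapter))
    stop("OCR engine 'easyocr' is not available on this system")
  f <- tempfile(fileext = ".png")
  on.exit(unlink(f))
  writeLabelImage(img, f)
  code <- sprintf(
    "import easyocr; r = easyocr.Reader([%s], verbose=False); print('\\n'.join(r.readtext(%s, detail=0)))",
    paste(sprintf("'%s'", adapter@languages), collapse = ","),
    sprintf("'%s'", f))
  txt <- paste(system2("python", c("-c", shQuote(code)), stdout = TRUE),
               collapse = "\n")
  ocrStream(txt, "easyocr", img@variantApplied,
            img@metadata$labelId %||% "label")
})

#' Run an engine adapter on a label image
#'
#' @param adapter an \linkS4class{EngineAdapter}
#' @param img a \linkS4class{LabelImage}
#' @param ... passed to the engine
#' @return an \linkS4class{OCRStream} tagged with the engine id and the
#'   image's variant id
#' @export
runEngine <- function(adapter, img, ...) {
  if (!isAvailable(adapter))
    stop("OCR engine '", adapter@engineId,
         "' is not available; install it or drop its streams")
  transcribe(adapter, img, ...)
}

#' Simulate a noisy OCR reading of a known text
#'
#' Applies the \linkS4class{NoiseModel} per character: with probability
#' \code{subRate} the character is substituted (by a member of its confusion
#' class when it has one, otherwise by a random alphabet character), with
#' probability \code{delRate} it is deleted, otherwise it is kept; after each
#' position (and before the first) an insertion occurs with probability
#' \code{insRate}. Bit-for-bit reproducible given the seed; the applied event
#' counts are recorded in the stream metadata.
#'
#' @param truth the ground-truth text
#' @param model a \linkS4class{NoiseModel}
#' @param seed optional override of the model seed
#' @return an \linkS4class{OCRStream} with engine id
#'   \code{"simulated:noise"}
#' @export
simulateOCR <- function(truth, model = noiseModel(), seed = model@seed) {
  validObject(model)
  cls <- model@confusionClasses
  classOf <- function(ch) {
    for (g in cls) if (ch %in% g) return(setdiff(g, ch))
    NULL
  }
  res <- withSeed(seed, {
    src <- if (nchar(truth)) chars(truth) else character()
    n <- length(src)
    # per-character event draw: one uniform decides substitute/delete/keep
    u <- if (n) runif(n) else numeric()
    isSub <- u < model@subRate
    isDel <- !isSub & u < model@subRate + model@delRate
    out <- src
    for (i in which(isSub)) {
      mates <- classOf(src[i])
      out[i] <- if (!is.null(mates) && length(mates)) {
        if (length(mates) == 1) mates else sample(mates, 1)
      } else {
        cand <- setdiff(model@alphabet, src[i])
        sample(cand, 1)
      }
    }
    out[isDel] <- ""
    # insertions in the n + 1 inter-character gaps (incl. both ends)
    insAt <- runif(n + 1) < model@insRate
    nIns <- sum(insAt)
    if (nIns) {
      insChars <- sample(model@alphabet, nIns, replace = TRUE)
      pieces <- character(2 * n + 1)
      pieces[seq(2, 2 * n, by = 2)] <- out
      slots <- seq(1, 2 * n + 1, by = 2)
      pieces[slots[insAt]] <- insChars
      out <- pieces
    }
    list(text = paste(out, collapse = ""),
         events = c(sub = sum(isSub), ins = nIns, del = sum(isDel)))
  })
  ocrStream(res$text, "simulated:noise",
            metadata = list(events = res$events, seed = as.integer(seed)))
}
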