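#' @include utils.R
NULL

#' Engine adapter generics
#'
#' Every OCR engine is wrapped in an adapter object. \code{isAvailable} probes
#' whether the engine can run in this session; \code{transcribe} runs it on a
#' pre-processed label image and returns an \linkS4class{OCRStream}.
#' Unavailable adapters fail loudly -- they never return empty text.
#'
#' @param adapter an \linkS4class{EngineAdapter}
#' @param img a \linkS4class{LabelImage}
#' @param ... passed through to the engine (page segmentation mode etc.)
#' @return \code{isAvailable}: logical scalar. \code{transcribe}: an
#'   \linkS4class{OCRStream}.
#' @name engine-generics
#' @aliases transcribe isAvailable
NULL

#' @rdname engine-generics
#' @export
setGeneric("isAvailable", function(adapter) standardGeneric("isAvailable"))

#' @rdname engine-generics
#' @export
setGeneric("transcribe", function(adapter, img, ...) standardGeneric("transcribe"))
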