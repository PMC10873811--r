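#' @include boxes-classes.R
NULL

#' The four pre-processing variant identifiers
#'
#' Each variant is the cumulative chain of the previous one's steps:
#' V1 leaves the image untouched, V2 adds blur/scale/orient/deskew, V3 adds
#' Sauvola binarization on top of V2, and V4 adds despeckle/hole-filling on
#' top of V3.
#' @export
preprocVariants <- c("V1_none", "V2_deskew", "V3_binarize", "V4_denoise")

#' A grayscale or binary label image with provenance
#'
#' Pixels are stored as a numeric matrix, rows = y (top to bottom), columns =
#' x. Grayscale intensities are 0 (black ink) to 255 (white paper); binary
#' images contain only \{0, 1\} with 1 = foreground (ink). Every transform
#' appends a record to the provenance list, which is never rewritten, so a
#' processed image always carries the full report of the steps that created
#' it.
#'
#' @slot pixels numeric matrix
#' @slot binary logical; TRUE when pixels are \{0, 1\} foreground masks
#' @slot variantApplied one of \code{preprocVariants}, or \code{"raw"}
#' @slot provenance list of \code{list(step =, params =)} records, append-only
#' @slot metadata free-form list (the synthetic renderer stores the ground
#'   truth text and skew here for oracle use)
#' @export
setClass("LabelImage",
  representation(pixels = "matrix", binary = "logical",
                 variantApplied = "character", provenance = "list",
                 metadata = "list"),
  prototype(binary = FALSE, variantApplied = "raw", provenance = list(),
            metadata = list()),
  validity = function(object) {
    msg <- character()
    if (nrow(object@pixels) < 1 || ncol(object@pixels) < 1)
      msg <- c(msg, "image must be at least 1x1")
    if (object@binary && !all(object@pixels %in% c(0, 1)))
      msg <- c(msg, "binary image must contain only 0 and 1")
    if (!object@binary &&
        (min(object@pixels) < 0 || max(object@pixels) > 255))
      msg <- c(msg, "grayscale intensities must lie in [0, 255]")
    if (length(msg)) msg else TRUE
  })

#' @param pixels numeric matrix (rows = y)
#' @param binary logical
#' @param metadata optional list
#' @rdname LabelImage-class
#' @export
labelImage <- function(pixels, binary = FALSE, metadata = list()) {
  new("LabelImage", pixels = pixels, binary = binary, metadata = metadata)
}

#' @rdname LabelImage-class
#' @param img a \code{LabelImage}
#' @export
imgWidth <- function(img) ncol(img@pixels)

#' @rdname LabelImage-class
#' @export
imgHeight <- function(img) nrow(img@pixels)

#' @rdname LabelImage-class
#' @export
imgPixels <- function(img) img@pixels

#' @rdname LabelImage-class
#' @export
imgProvenance <- function(img) img@provenance

setMethod("show", "LabelImage", function(object) {
  cat(sprintf("LabelImage %dx%d px, %s, variant %s, %d provenance step(s)\n",
              imgWidth(object), imgHeight(object),
              if (object@binary) "binary" else "grayscale",
              object@variantApplied, length(object@provenance)))
})

# internal: return a modified copy with a provenance record appended
withStep <- function(img, pixels, step, params = list(), binary = img@binary,
                     variant = img@variantApplied) {
  new("LabelImage", pixels = pixels, binary = binary,
      variantApplied = variant,
      provenance = c(img@provenance, list(list(step = step, params = params))),
      metadata = img@metadata)
}

#' Pre-processing parameter set
#'
#' Bundles the tunable knobs of the variant chain. The defaults were chosen
#' for typewritten label images a few thousand pixels across; all are
#' configurable.
#'
#' @param blurRadius Gaussian blur sigma in pixels (0 disables)
#' @param targetLongSide isotropic rescale target for the longer image side,
#'   pixels (NULL disables)
#' @param sauvolaWindow odd local-window size for Sauvola thresholding
#' @param sauvolaK Sauvola sensitivity parameter, in (0, 1)
#' @param sauvolaR Sauvola dynamic range of the standard deviation
#' @param minSpeck foreground components smaller than this many pixels are
#'   removed as "snow"
#' @param minHole enclosed background components smaller than this are filled
#' @param maxSkew deskew search half-range, degrees
#' @param skewStep deskew search grid step, degrees
#' @return a named list of parameters
#' @export
preprocParams <- function(blurRadius = 0.5, targetLongSide = 4096,
                          sauvolaWindow = 31, sauvolaK = 0.2, sauvolaR = 128,
                          minSpeck = 4, minHole = 4,
                          maxSkew = 10, skewStep = 0.1) {
  list(blurRadius = blurRadius, targetLongSide = targetLongSide,
       sauvolaWindow = sauvolaWindow, sauvolaK = sauvolaK, sauvolaR = sauvolaR,
       minSpeck = minSpeck, minHole = minHole,
       maxSkew = maxSkew, skewStep = skewStep)
}
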