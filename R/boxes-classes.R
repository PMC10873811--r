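#' @include AllGenerics.R
NULL

#' Closed vocabulary of label types
#'
#' The five classes participants (and models) assign to a label on a
#' herbarium sheet.
#' @export
labelTypes <- c("typewritten", "handwritten", "both", "barcode", "other")

#' Axis-aligned bounding box on a sheet or label image
#'
#' Coordinates are 0-based pixel indices; a box is stored as inclusive-min /
#' exclusive-max, so its area is \code{(xMax - xMin) * (yMax - yMin)}.
#' Degenerate (zero-area) boxes are rejected by the validity method.
#'
#' @slot xMin,yMin,xMax,yMax numeric pixel coordinates, \code{xMin < xMax},
#'   \code{yMin < yMax}, all non-negative.
#' @export
setClass("BoundingBox",
  representation(xMin = "numeric", yMin = "numeric",
                 xMax = "numeric", yMax = "numeric"),
  validity = function(object) {
    msg <- character()
    v <- c(object@xMin, object@yMin, object@xMax, object@yMax)
    if (length(v) != 4 || anyNA(v)) msg <- c(msg, "all four coordinates must be non-missing scalars")
    else {
      if (any(v < 0)) msg <- c(msg, "coordinates must be >= 0")
      if (!(object@xMin < object@xMax)) msg <- c(msg, "xMin must be < xMax")
      if (!(object@yMin < object@yMax)) msg <- c(msg, "yMin must be < yMax")
    }
    if (length(msg)) msg else TRUE
  })

#' @param xMin,yMin,xMax,yMax pixel coordinates
#' @return a \code{BoundingBox}
#' @rdname BoundingBox-class
#' @examples
#' boundingBox(0, 0, 10, 10)
#' @export
boundingBox <- function(xMin, yMin, xMax, yMax) {
  new("BoundingBox", xMin = as.numeric(xMin), yMin = as.numeric(yMin),
      xMax = as.numeric(xMax), yMax = as.numeric(yMax))
}

#' @rdname BoundingBox-class
#' @param box a \code{BoundingBox}
#' @export
boxArea <- function(box) (box@xMax - box@xMin) * (box@yMax - box@yMin)

#' @rdname BoundingBox-class
#' @export
boxCoords <- function(box) c(xMin = box@xMin, yMin = box@yMin,
                             xMax = box@xMax, yMax = box@yMax)

setMethod("show", "BoundingBox", function(object) {
  cat(sprintf("BoundingBox [%g, %g, %g, %g] (area %g)\n",
              object@xMin, object@yMin, object@xMax, object@yMax,
              boxArea(object)))
})

#' One participant's (or model's) label annotation
#'
#' @slot box the drawn \linkS4class{BoundingBox}
#' @slot labelType one of \code{labelTypes}
#' @slot sourceId annotator or model identifier
#' @export
setClass("LabelAnnotation",
  representation(box = "BoundingBox", labelType = "character",
                 sourceId = "character"),
  validity = function(object) {
    if (length(object@labelType) != 1 || !(object@labelType %in% labelTypes))
      return(sprintf("labelType must be one of: %s",
                     paste(labelTypes, collapse = ", ")))
    TRUE
  })

#' @param box a \linkS4class{BoundingBox}
#' @param labelType one of \code{labelTypes}
#' @param sourceId annotator/model id
#' @rdname LabelAnnotation-class
#' @export
labelAnnotation <- function(box, labelType, sourceId = "anonymous") {
  new("LabelAnnotation", box = box, labelType = labelType,
      sourceId = as.character(sourceId))
}

setMethod("show", "LabelAnnotation", function(object) {
  cat(sprintf("LabelAnnotation <%s> %s [%g, %g, %g, %g]\n", object@sourceId,
              object@labelType, object@box@xMin, object@box@yMin,
              object@box@xMax, object@box@yMax))
})

#' Consensus of several outlines of one physical label
#'
#' Produced by \code{\link{reconcileAnnotations}}: the average outline of the
#' surviving (non-outlier) participant boxes plus the majority-rule type.
#'
#' @slot box averaged \linkS4class{BoundingBox}
#' @slot labelType majority class, or \code{"unresolved"}
#' @slot nContributing number of outlines averaged (>= 1)
#' @slot outliersRemoved number of outlines dropped as outliers
#' @slot resolved whether a strict type majority existed
#' @export
setClass("ReconciledLabel",
  representation(box = "BoundingBox", labelType = "character",
                 nContributing = "integer", outliersRemoved = "integer",
                 resolved = "logical"),
  validity = function(object) {
    msg <- character()
    if (object@nContributing < 1L) msg <- c(msg, "nContributing must be >= 1")
    if (!(object@labelType %in% c(labelTypes, "unresolved")))
      msg <- c(msg, "labelType must be a known class or 'unresolved'")
    if (object@resolved && object@labelType == "unresolved")
      msg <- c(msg, "a resolved label cannot have type 'unresolved'")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "ReconciledLabel", function(object) {
  cat(sprintf(
    "ReconciledLabel %s [%g, %g, %g, %g] (%d outlines, %d outliers removed%s)\n",
    object@labelType, object@box@xMin, object@box@yMin, object@box@xMax,
    object@box@yMax, object@nContributing, object@outliersRemoved,
    if (object@resolved) "" else ", UNRESOLVED type"))
})

#' A correct/incorrect/missed click from the correction expedition
#'
#' @slot x,y pixel coordinates of the click
#' @slot verdict one of \code{"correct"}, \code{"incorrect"}, \code{"missed"}
#' @slot targetSheet sheet identifier
#' @export
setClass("CorrectionClick",
  representation(x = "numeric", y = "numeric", verdict = "character",
                 targetSheet = "character"),
  validity = function(object) {
    if (!(object@verdict %in% c("correct", "incorrect", "missed")))
      return("verdict must be one of: correct, incorrect, missed")
    TRUE
  })

#' @param x,y click coordinates
#' @param verdict one of correct/incorrect/missed
#' @param targetSheet sheet id
#' @rdname CorrectionClick-class
#' @export
correctionClick <- function(x, y, verdict, targetSheet = "sheet") {
  new("CorrectionClick", x = as.numeric(x), y = as.numeric(y),
      verdict = verdict, targetSheet = as.character(targetSheet))
}
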