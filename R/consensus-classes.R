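#' @include similarity.R
NULL

#' The reserved gap sentinel
#'
#' MSA rows use a reserved non-printable code point (U+001F, unit separator)
#' as the gap symbol; it is rejected in any input text.
#' @return single character string
#' @export
gapChar <- function() "\037"

#' Affine gap penalties for the visual-similarity alignment
#'
#' The first gap symbol in a run costs \code{gapOpen} and each subsequent one
#' \code{gapExtend}. Defaults are the pipeline's heuristically determined
#' values: open -3, extend -0.5.
#'
#' @slot gapOpen,gapExtend non-positive reals with
#'   \code{gapOpen <= gapExtend <= 0}
#' @export
setClass("AlignmentParams",
  representation(gapOpen = "numeric", gapExtend = "numeric"),
  validity = function(object) {
    if (!(object@gapOpen <= object@gapExtend && object@gapExtend <= 0))
      return("need gapOpen <= gapExtend <= 0")
    TRUE
  })

#' @param gapOpen,gapExtend gap penalties (non-positive)
#' @rdname AlignmentParams-class
#' @export
alignmentParams <- function(gapOpen = -3, gapExtend = -0.5) {
  new("AlignmentParams", gapOpen = gapOpen, gapExtend = gapExtend)
}

setMethod("show", "AlignmentParams", function(object) {
  cat(sprintf("AlignmentParams(gapOpen = %g, gapExtend = %g)\n",
              object@gapOpen, object@gapExtend))
})

#' A multiple sequence alignment of OCR streams
#'
#' All rows have equal length; removing the gap sentinels from row i
#' reproduces stream i's text exactly (validity-enforced on construction
#' against the stored ungapped texts).
#'
#' @slot rows character vector of gapped sequences (gap =
#'   \code{\link{gapChar}})
#' @slot streamIds identifiers of the aligned streams, parallel to rows
#' @slot seedIndex index of the seed (most central) stream within rows
#' @export
setClass("MSAResult",
  representation(rows = "character", streamIds = "character",
                 seedIndex = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@rows) < 1) msg <- c(msg, "at least one row required")
    if (length(unique(nchar(object@rows))) > 1)
      msg <- c(msg, "all rows must have equal length")
    if (length(object@streamIds) != length(object@rows))
      msg <- c(msg, "one stream id per row required")
    if (object@seedIndex < 1 || object@seedIndex > length(object@rows))
      msg <- c(msg, "seedIndex out of range")
    if (length(msg)) msg else TRUE
  })

#' @rdname MSAResult-class
#' @param msa an \code{MSAResult}
#' @export
msaRows <- function(msa) msa@rows

#' @rdname MSAResult-class
#' @export
msaColumnCount <- function(msa) nchar(msa@rows[1])

setMethod("show", "MSAResult", function(object) {
  cat(sprintf("MSAResult: %d rows x %d columns (seed row %d)\n",
              length(object@rows), msaColumnCount(object), object@seedIndex))
  disp <- gsub(gapChar(), "-", object@rows, fixed = TRUE)
  for (i in seq_along(disp)) {
    d <- disp[i]
    if (nchar(d) > 60) d <- paste0(substr(d, 1, 57), "...")
    cat(sprintf("  [%s] %s\n", object@streamIds[i], d))
  }
})

#' A consensus transcription with per-column support
#'
#' @slot text the consensus text (contains no gap sentinel)
#' @slot support fraction of rows voting for each emitted character, in
#'   (0, 1]; empty once post-processing has rewritten the text, since the
#'   column-to-character mapping no longer holds
#' @slot prunedStreamIds streams removed as Levenshtein outliers before
#'   alignment
#' @slot metadata free-form list (the pipeline stores the post-processing
#'   change log here)
#' @export
setClass("ConsensusText",
  representation(text = "character", support = "numeric",
                 prunedStreamIds = "character", metadata = "list"),
  prototype(prunedStreamIds = character(), metadata = list()),
  validity = function(object) {
    msg <- character()
    if (grepl(gapChar(), object@text, fixed = TRUE))
      msg <- c(msg, "consensus text must not contain the gap sentinel")
    if (!length(object@support) %in% c(0L, nchar(object@text)))
      msg <- c(msg, "one support value per character (or none) required")
    if (length(object@support) &&
        (min(object@support) <= 0 || max(object@support) > 1))
      msg <- c(msg, "support values must lie in (0, 1]")
    if (length(msg)) msg else TRUE
  })

#' @rdname ConsensusText-class
#' @param x a \code{ConsensusText}
#' @export
consensusText <- function(x) x@text

#' @rdname ConsensusText-class
#' @export
consensusSupport <- function(x) x@support

setMethod("show", "ConsensusText", function(object) {
  txt <- object@text
  if (nchar(txt) > 60) txt <- paste0(substr(txt, 1, 57), "...")
  cat(sprintf("ConsensusText (%d chars, %s%s): \"%s\"\n",
              nchar(object@text),
              if (length(object@support))
                sprintf("mean support %.2f", mean(object@support))
              else "post-processed",
              if (length(object@prunedStreamIds))
                sprintf(", %d stream(s) pruned", length(object@prunedStreamIds))
              else "",
              txt))
})
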