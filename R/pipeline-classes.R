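#' @include synthetic.R
NULL

#' One OCR pipeline permutation
#'
#' A configuration of the ensemble: a nonempty subset of the eight
#' (pre-processing variant, engine) streams plus the post-processing on/off
#' flag. Crossing every nonempty subset with the flag gives the full sweep of
#' (2^8 - 1) * 2 = 510 permutations.
#'
#' @slot streams character subset of \code{\link{streamCombos}}, nonempty
#' @slot postprocess logical flag
#' @export
setClass("Permutation",
  representation(streams = "character", postprocess = "logical"),
  validity = function(object) {
    msg <- character()
    if (length(object@streams) < 1) msg <- c(msg, "stream set must be nonempty")
    if (anyDuplicated(object@streams)) msg <- c(msg, "duplicate stream ids")
    if (!all(object@streams %in% streamCombos()))
      msg <- c(msg, "unknown stream id")
    if (length(msg)) msg else TRUE
  })

#' @param streams stream combination ids
#' @param postprocess logical
#' @rdname Permutation-class
#' @export
permutation <- function(streams, postprocess = FALSE) {
  new("Permutation", streams = streams, postprocess = postprocess)
}

#' @rdname Permutation-class
#' @param perm a \code{Permutation}
#' @export
permutationId <- function(perm) {
  yn <- ifelse(streamCombos() %in% perm@streams, "Y", "N")
  paste0(paste(yn, collapse = ""), if (perm@postprocess) "+post" else "-post")
}

setMethod("show", "Permutation", function(object) {
  cat(sprintf("Permutation [%s] postprocess=%s\n",
              paste(object@streams, collapse = ", "),
              object@postprocess))
})

#' Pipeline configuration bundle
#'
#' Collects everything a permutation run needs: the similarity matrix and
#' alignment parameters, the Levenshtein outlier cutoff, the pre- and
#' post-substitution rules, the correction lexicon, the engine adapters and
#' the pre-processing parameters.
#'
#' @param matrix a \linkS4class{SimilarityMatrix}
#' @param align an \linkS4class{AlignmentParams}
#' @param cutoff Levenshtein outlier cutoff
#' @param preRules pre-alignment substitution rules
#' @param postRules post-consensus substitution rules
#' @param lexicon a \linkS4class{Lexicon} (or NULL to disable spell repair)
#' @param engines named list of \linkS4class{EngineAdapter}s keyed by engine
#'   name ("easyocr", "tesseract", ...)
#' @param preproc a \code{\link{preprocParams}} list
#' @return a named list
#' @export
pipelineConfig <- function(matrix = defaultSimilarityMatrix(),
                           align = alignmentParams(),
                           cutoff = 128,
                           preRules = defaultPreRules(),
                           postRules = defaultSubstitutionRules(),
                           lexicon = defaultLexicon(),
                           engines = list(),
                           preproc = preprocParams()) {
  list(matrix = matrix, align = align, cutoff = cutoff, preRules = preRules,
       postRules = postRules, lexicon = lexicon, engines = engines,
       preproc = preproc)
}

#' Evaluation report against a verbatim gold standard
#'
#' @slot summary data.frame, one row per evaluated permutation: a Y/N column
#'   per stream combination, \code{postprocess}, \code{total_errors} and
#'   \code{rank} (ascending by cumulative error)
#' @slot perLabel data.frame: \code{perm_id}, \code{label_id}, \code{error},
#'   \code{missing}
#' @slot provenance list (package version, config and matrix hashes, gold
#'   size)
#' @export
setClass("EvaluationReport",
  representation(summary = "data.frame", perLabel = "data.frame",
                 provenance = "list"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@summary)) {
      agg <- tapply(object@perLabel$error, object@perLabel$perm_id, sum)
      tot <- object@summary$total_errors[match(names(agg),
                                               object@summary$perm_id)]
      if (any(abs(agg - tot) > 1e-9))
        msg <- c(msg, "total_errors must equal the sum of per-label errors")
      if (is.unsorted(object@summary$total_errors))
        msg <- c(msg, "summary must be ranked ascending by total_errors")
    }
    if (length(msg)) msg else TRUE
  })

#' @rdname EvaluationReport-class
#' @param report an \code{EvaluationReport}
#' @export
rankingTable <- function(report) report@summary

#' @rdname EvaluationReport-class
#' @export
perLabelErrors <- function(report) report@perLabel

#' @rdname EvaluationReport-class
#' @export
reportProvenance <- function(report) report@provenance

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport: %d permutation(s) x %d label(s)\n",
              nrow(object@summary),
              length(unique(object@perLabel$label_id))))
  if (nrow(object@summary)) {
    best <- object@summary[1, ]
    cat(sprintf("  best: %s with %g cumulative errors\n", best$perm_id,
                best$total_errors))
  }
})
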