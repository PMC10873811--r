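#' @include pipeline.R
NULL

.normalizeText <- function(x, normalization) {
  switch(normalization,
         none = x,
         strip = trimws(x),
         collapse_ws = gsub("[ \t]+", " ", trimws(x)),
         stop("unknown normalization: ", normalization))
}

.reportProvenance <- function(cfg, extra = list()) {
  c(list(package = "herbocr",
         version = as.character(packageVersion("herbocr")),
         configHash = configHash(list(
           cutoff = cfg$cutoff,
           gapOpen = cfg$align@gapOpen, gapExtend = cfg$align@gapExtend,
           preRules = cfg$preRules, postRules = cfg$postRules)),
         matrixHash = configHash(list(classes = cfg$matrix@classes,
                                      within = cfg$matrix@withinScore,
                                      overrides = cfg$matrix@overrides))),
    extra)
}

#' Score transcriptions against the verbatim gold standard
#'
#' Per label, the error is the Levenshtein distance between the produced
#' text and the verbatim gold transcription after the configured
#' normalization (default: strip leading/trailing whitespace only -- the
#' verbatim rubric forbids anything stronger). The cumulative error is the
#' sum over labels. A label with no output counts its full gold length as
#' error and is flagged missing.
#'
#' @param outputs named character vector or list, names = label ids
#' @param gold data.frame with \code{label_id} and verbatim \code{text}
#' @param normalization one of \code{"strip"}, \code{"none"},
#'   \code{"collapse_ws"}
#' @param permId identifier for this output set in the report
#' @param cfg a \code{\link{pipelineConfig}} (only provenance fields are
#'   used)
#' @return an \linkS4class{EvaluationReport} with a single summary row
#' @export
evaluateTranscriptions <- function(outputs, gold, normalization = "strip",
                                   permId = "output",
                                   cfg = pipelineConfig()) {
  if (anyDuplicated(gold$label_id))
    stop("duplicate label_id in gold standard")
  outputs <- unlist(outputs)
  err <- numeric(nrow(gold))
  miss <- logical(nrow(gold))
  for (i in seq_len(nrow(gold))) {
    gtxt <- .normalizeText(gold$text[i], normalization)
    o <- outputs[gold$label_id[i]]
    if (is.null(o) || is.na(o)) {
      err[i] <- nchar(gtxt)
      miss[i] <- TRUE
    } else {
      err[i] <- levenshtein(.normalizeText(o, normalization), gtxt)
    }
  }
  perLabel <- data.frame(perm_id = permId, label_id = gold$label_id,
                         error = err, missing = miss,
                         stringsAsFactors = FALSE)
  summary <- data.frame(perm_id = permId, total_errors = sum(err),
                        rank = 1L, stringsAsFactors = FALSE)
  new("EvaluationReport", summary = summary, perLabel = perLabel,
      provenance = .reportProvenance(cfg, list(
        nLabels = nrow(gold), normalization = normalization)))
}

#' Sweep pipeline permutations against a gold standard
#'
#' Runs every requested permutation over every label and ranks them by
#' cumulative error, reproducing the permutation-table layout (one Y/N
#' column per stream combination, the post-processing flag, total errors).
#' Streams are computed once per (variant, engine, label) and shared across
#' permutations; the consensus is likewise computed once per stream subset
#' and reused for the post-processing on/off pair, which never changes the
#' result relative to independent recomputation.
#'
#' @param streamSets named list: label id -> named list of
#'   \linkS4class{OCRStream}s covering \code{\link{streamCombos}} (use
#'   \code{\link{simulateStreamSet}} for fixtures, or build them with
#'   \code{\link{applyVariant}} + \code{\link{runEngine}})
#' @param gold data.frame with \code{label_id}, \code{text}
#' @param permutations list of \linkS4class{Permutation}s (default: the full
#'   510)
#' @param cfg a \code{\link{pipelineConfig}}
#' @param normalization see \code{\link{evaluateTranscriptions}}
#' @return an \linkS4class{EvaluationReport}
#' @export
sweepPermutations <- function(streamSets, gold,
                              permutations = enumeratePermutations(),
                              cfg = pipelineConfig(),
                              normalization = "strip") {
  if (anyDuplicated(gold$label_id))
    stop("duplicate label_id in gold standard")
  combos <- streamCombos()
  # consensus (pre-postprocess) cache keyed by stream subset
  rawCache <- new.env(parent = emptyenv())
  rawFor <- function(perm) {
    key <- paste(sort(perm@streams), collapse = "|")
    if (!is.null(rawCache[[key]])) return(rawCache[[key]])
    noPost <- permutation(perm@streams, FALSE)
    outs <- vapply(gold$label_id, function(lid)
      consensusText(runPermutation(streamSets[[lid]], noPost, cfg)),
      character(1))
    rawCache[[key]] <- outs
    outs
  }
  perLabel <- vector("list", length(permutations))
  rows <- vector("list", length(permutations))
  for (k in seq_along(permutations)) {
    perm <- permutations[[k]]
    outs <- rawFor(perm)
    if (perm@postprocess) {
      outs <- vapply(outs, function(t)
        postCleanup(t, cfg$postRules, cfg$lexicon)$text, character(1))
    }
    rep1 <- evaluateTranscriptions(outs, gold, normalization,
                                   permId = permutationId(perm), cfg)
    perLabel[[k]] <- perLabelErrors(rep1)
    yn <- as.list(ifelse(combos %in% perm@streams, "Y", "N"))
    names(yn) <- combos
    rows[[k]] <- cbind(data.frame(perm_id = permutationId(perm),
                                  stringsAsFactors = FALSE),
                       as.data.frame(yn, optional = TRUE),
                       data.frame(postprocess = ifelse(perm@postprocess,
                                                       "Y", "N"),
                                  total_errors = rankingTable(rep1)$total_errors))
  }
  summary <- do.call(rbind, rows)
  ord <- order(summary$total_errors, summary$perm_id)
  summary <- summary[ord, , drop = FALSE]
  summary$rank <- seq_len(nrow(summary))
  rownames(summary) <- NULL
  new("EvaluationReport", summary = summary,
      perLabel = do.call(rbind, perLabel),
      provenance = .reportProvenance(cfg, list(
        nLabels = nrow(gold), nPermutations = length(permutations),
        normalization = normalization)))
}

#' Write a permutation report as TSV
#'
#' Mirrors the permutation-table layout: one Y/N column per stream
#' combination, the post-processing flag and the cumulative error, ranked
#' ascending.
#'
#' @param report an \linkS4class{EvaluationReport}
#' @param path output TSV path
#' @export
writeReportTSV <- function(report, path) {
  utils::write.table(rankingTable(report), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
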