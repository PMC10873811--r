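#' @include pipeline-classes.R
NULL

#' Enumerate all pipeline permutations
#'
#' Every nonempty subset of the eight (variant, engine) streams crossed with
#' the post-processing flag: (2^8 - 1) * 2 = 510 distinct configurations, in
#' a deterministic canonical order (subsets by bitmask over
#' \code{\link{streamCombos}}, post-processing off before on).
#'
#' @return list of \linkS4class{Permutation}s, length 510
#' @export
enumeratePermutations <- function() {
  combos <- streamCombos()
  out <- vector("list", (2^length(combos) - 1) * 2)
  k <- 0L
  for (mask in seq_len(2^length(combos) - 1)) {
    sel <- combos[bitwAnd(mask, bitwShiftL(1L, seq_along(combos) - 1L)) != 0L]
    for (post in c(FALSE, TRUE)) {
      k <- k + 1L
      out[[k]] <- permutation(sel, post)
    }
  }
  out
}

#' Run one pipeline permutation on one label
#'
#' Composes the module operations end to end: per included stream, the
#' pre-processing variant and engine (or a precomputed stream), then the
#' pre-alignment substitutions, Levenshtein outlier pruning, progressive MSA,
#' consensus calling, and -- iff the permutation asks for it -- the
#' post-consensus cleanup. A single-stream permutation skips pruning and
#' alignment (the consensus of one stream is itself, cleaned the same way).
#'
#' @param x either a named list of precomputed \linkS4class{OCRStream}s
#'   (names from \code{\link{streamCombos}}) or a \linkS4class{LabelImage},
#'   in which case the configured engine adapters are run
#' @param perm a \linkS4class{Permutation}
#' @param cfg a \code{\link{pipelineConfig}} list
#' @return a \linkS4class{ConsensusText}; the post-processing change log, if
#'   any, is in \code{metadata$changes}
#' @export
runPermutation <- function(x, perm, cfg = pipelineConfig()) {
  validObject(perm)
  if (is(x, "LabelImage")) {
    streams <- list()
    for (combo in perm@streams) {
      parts <- strsplit(combo, ".", fixed = TRUE)[[1]]
      adapter <- cfg$engines[[parts[2]]]
      if (is.null(adapter) || !isAvailable(adapter))
        stop("permutation requires engine '", parts[2],
             "', which is not available and no precomputed stream was given")
      imgV <- applyVariant(x, parts[1], cfg$preproc)
      streams[[combo]] <- runEngine(adapter, imgV)
    }
  } else {
    missing <- setdiff(perm@streams, names(x))
    if (length(missing))
      stop("no precomputed stream for: ", paste(missing, collapse = ", "))
    streams <- x[perm@streams]
  }
  streams <- lapply(streams, function(s) {
    s@text <- preSubstitutions(streamText(s), cfg$preRules)
    s
  })
  if (length(streams) == 1) {
    txt <- streamText(streams[[1]])
    ct <- new("ConsensusText", text = txt,
              support = rep(1, nchar(txt)), prunedStreamIds = character())
  } else {
    texts <- vapply(streams, streamText, character(1))
    d <- .levPairwise(texts, cap = max(256, cfg$cutoff + 1))
    pruned <- pruneOutliers(unname(streams), cfg$cutoff, dists = d)
    msa <- buildMSA(pruned$streams, cfg$matrix, cfg$align,
                    dists = d[pruned$keep, pruned$keep, drop = FALSE])
    ct <- callConsensus(msa)
    ct@prunedStreamIds <- pruned$prunedIds
  }
  if (isTRUE(perm@postprocess)) {
    cleaned <- postCleanup(ct@text, cfg$postRules, cfg$lexicon)
    ct <- new("ConsensusText", text = cleaned$text, support = numeric(),
              prunedStreamIds = ct@prunedStreamIds,
              metadata = list(changes = cleaned$changes,
                              rawConsensus = ct@text))
  }
  ct
}

#' Read and write verbatim gold-standard TSV
#'
#' Two tab-separated columns with header \code{label_id<TAB>text}, UTF-8.
#' Literal tabs and newlines inside a transcription are escaped as
#' \code{\\t} and \code{\\n}; backslashes as \code{\\\\}.
#'
#' @param path TSV file
#' @return data.frame with \code{label_id}, \code{text}
#' @export
readGoldTSV <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (!length(lines) || !identical(lines[1], "label_id\ttext"))
    stop("gold TSV must start with header 'label_id\\ttext'")
  lines <- lines[-1]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2))
    stop("gold TSV rows must have exactly two tab-separated fields")
  unescape1 <- function(x) {
    cs <- chars(x)
    out <- character(); i <- 1L
    while (i <= length(cs)) {
      if (cs[i] == "\\" && i < length(cs)) {
        nx <- cs[i + 1L]
        out <- c(out, switch(nx, n = "\n", t = "\t", "\\" = "\\",
                             paste0("\\", nx)))
        i <- i + 2L
      } else {
        out <- c(out, cs[i]); i <- i + 1L
      }
    }
    paste(out, collapse = "")
  }
  data.frame(label_id = vapply(parts, `[`, "", 1),
             text = vapply(vapply(parts, `[`, "", 2), unescape1, "",
                           USE.NAMES = FALSE),
             stringsAsFactors = FALSE)
}

#' @rdname readGoldTSV
#' @param gold data.frame with \code{label_id}, \code{text}
#' @export
writeGoldTSV <- function(gold, path) {
  escape <- function(x) {
    x <- gsub("\\", "\\\\", x, fixed = TRUE)
    x <- gsub("\t", "\\t", x, fixed = TRUE)
    gsub("\n", "\\n", x, fixed = TRUE)
  }
  writeLines(c("label_id\ttext",
               paste(gold$label_id, escape(gold$text), sep = "\t")),
             path, useBytes = TRUE)
  invisible(path)
}
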