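#' @include consensus-classes.R
NULL

#' Levenshtein edit distance
#'
#' Minimum number of single-character substitutions, insertions and deletions
#' converting one string into the other (unit costs), computed by the
#' package's rolling-row dynamic program in C++.
#'
#' @param a a character string
#' @param b character string(s); vectorized
#' @return non-negative integer(s)
#' @examples
#' levenshtein("kitten", "sitting")  # 3
#' @export
levenshtein <- function(a, b) {
  ca <- utf8ToInt(a)
  vapply(b, function(x) lev_full_cpp(ca, utf8ToInt(x)), integer(1),
         USE.NAMES = FALSE)
}

# pairwise distance matrix, exact up to `cap` (larger distances are reported
# as cap + 1, which is all the outlier rule and merge ordering need)
.levPairwise <- function(texts, cap) {
  lev_pairwise_cpp(lapply(texts, utf8ToInt), as.integer(cap))
}

#' Prune outlier OCR streams before alignment
#'
#' Complete OCR failures (a blank or garbled stream) would poison the
#' alignment, so any stream whose Levenshtein distance from the two closest
#' streams exceeds the cutoff is removed first: the globally closest pair is
#' the anchor, and a stream survives iff its smaller distance to either
#' anchor is within the cutoff. With one or two streams nothing is pruned,
#' and the anchor pair always survives, so at most \code{n - 2} streams are
#' ever removed.
#'
#' @param streams list of \linkS4class{OCRStream}s
#' @param cutoff Levenshtein cutoff (default 128, determined upstream by
#'   trial and error)
#' @param dists optional precomputed pairwise distance matrix (exact at
#'   least up to \code{cutoff}); computed when NULL
#' @return list with \code{streams} (survivors, original order) and
#'   \code{prunedIds} (engine/variant tags of removed streams)
#' @export
pruneOutliers <- function(streams, cutoff = 128, dists = NULL) {
  stopifnot(length(streams) >= 1)
  n <- length(streams)
  if (n <= 2)
    return(list(streams = streams, prunedIds = character(),
                keep = rep(TRUE, n)))
  texts <- vapply(streams, streamText, character(1))
  d <- if (is.null(dists)) .levPairwise(texts, cap = cutoff + 1) else dists
  diag(d) <- Inf
  pair <- which(d == min(d), arr.ind = TRUE)[1, ]
  anchors <- sort(unname(pair))
  keep <- vapply(seq_len(n), function(i) {
    if (i %in% anchors) return(TRUE)
    min(d[i, anchors]) <= cutoff
  }, logical(1))
  ids <- vapply(streams, function(s) paste(s@variantId, s@engineId, sep = "."),
                character(1))
  list(streams = streams[keep], prunedIds = ids[!keep], keep = keep)
}

#' Pre-alignment text substitutions
#'
#' Fixes errors the OCR engines commonly introduce before the streams are
#' aligned: spurious whitespace in front of punctuation, runs of spaces, and
#' any configured character substitutions. The default rule list is
#' idempotent.
#'
#' @param text character string
#' @param rules data.frame(pattern, replacement) of ordered regex rules
#' @return the corrected text
#' @examples
#' preSubstitutions("Austin , Texas .")  # "Austin, Texas."
#' @export
preSubstitutions <- function(text, rules = defaultPreRules()) {
  for (i in seq_len(nrow(rules))) {
    text <- gsub(rules$pattern[i], rules$replacement[i], text, perl = TRUE)
  }
  text
}

#' @rdname preSubstitutions
#' @export
defaultPreRules <- function() {
  data.frame(
    pattern = c("[ \t]+([.,;:])", "  +"),
    replacement = c("\\1", " "),
    stringsAsFactors = FALSE)
}

# internal: map texts to integer code rows over a common alphabet
.encode <- function(text, alphabet) {
  if (!nchar(text)) return(integer())
  match(chars(text), alphabet)
}

#' Global pairwise alignment under the visual-similarity matrix
#'
#' Needleman-Wunsch/Gotoh alignment maximizing the summed column score with
#' affine gap costs: the first gap character of a run costs \code{gapOpen},
#' each further one \code{gapExtend}. Ties prefer a match/mismatch column
#' over a gap, then a gap in the second sequence.
#'
#' @param a,b strings to align (must not contain the gap sentinel)
#' @param m a \linkS4class{SimilarityMatrix}
#' @param p an \linkS4class{AlignmentParams}
#' @return list with \code{alignedA}, \code{alignedB} (gapped strings) and
#'   \code{score}
#' @export
pairwiseAlign <- function(a, b, m = defaultSimilarityMatrix(),
                          p = alignmentParams()) {
  if (grepl(gapChar(), a, fixed = TRUE) || grepl(gapChar(), b, fixed = TRUE))
    stop("input text contains the reserved gap sentinel")
  alphabet <- unique(c(chars(a), chars(b)))
  if (!length(alphabet)) {
    return(list(alignedA = "", alignedB = "", score = 0))
  }
  sim <- scoreMatrix(m, alphabet)
  prof <- matrix(.encode(a, alphabet), nrow = 1)
  res <- gotoh_profile_align(prof, .encode(b, alphabet), sim,
                             p@gapOpen, p@gapExtend)
  ca <- chars(a); cb <- chars(b)
  g <- gapChar()
  outA <- ifelse(res$prof_idx > 0, ca[pmax(res$prof_idx, 1)], g)
  outB <- ifelse(res$seq_idx > 0, cb[pmax(res$seq_idx, 1)], g)
  list(alignedA = paste(outA, collapse = ""),
       alignedB = paste(outB, collapse = ""),
       score = res$score)
}

#' Progressive multiple sequence alignment of OCR streams
#'
#' Center-star-style progressive alignment: the seed is the most central
#' stream (minimum summed Levenshtein distance to the others), and the
#' remaining streams are aligned to the growing profile in ascending distance
#' from the seed. A character is scored against a profile column by its mean
#' similarity to the column's non-gap symbols; once a gap column is
#' introduced it is never removed ("once a gap, always a gap"). A single
#' stream yields the trivial one-row alignment.
#'
#' @param streams list of \linkS4class{OCRStream}s (>= 1)
#' @param m a \linkS4class{SimilarityMatrix}
#' @param p an \linkS4class{AlignmentParams}
#' @param dists optional precomputed pairwise Levenshtein matrix used only
#'   for seed choice and merge order
#' @return an \linkS4class{MSAResult}; rows are ordered as the input streams
#' @export
buildMSA <- function(streams, m = defaultSimilarityMatrix(),
                     p = alignmentParams(), dists = NULL) {
  stopifnot(length(streams) >= 1)
  texts <- vapply(streams, streamText, character(1))
  if (any(grepl(gapChar(), texts, fixed = TRUE)))
    stop("input text contains the reserved gap sentinel")
  ids <- vapply(streams, function(s) paste(s@variantId, s@engineId, sep = "."),
                character(1))
  ids <- make.unique(ids)
  n <- length(texts)
  if (n == 1) {
    return(new("MSAResult", rows = texts, streamIds = ids, seedIndex = 1L))
  }
  d <- if (is.null(dists)) .levPairwise(texts, cap = 256) else dists
  seed <- which.min(rowSums(d))
  rest <- setdiff(seq_len(n), seed)
  rest <- rest[order(d[seed, rest], rest)]
  # canonical alphabet: the full printable set (plus anything unusual in the
  # inputs), in codepoint order -- keeps the dense score matrix cacheable
  alphabet <- unique(c(printableChars(), "\n",
                       unlist(strsplit(texts, "", fixed = TRUE))))
  alphabet <- alphabet[order(vapply(alphabet, function(ch) utf8ToInt(ch)[1],
                                    numeric(1)))]
  sim <- scoreMatrix(m, alphabet)
  # profile: integer code matrix, rows = already-aligned streams, 0 = gap
  prof <- matrix(.encode(texts[seed], alphabet), nrow = 1)
  members <- seed
  for (i in rest) {
    seqi <- .encode(texts[i], alphabet)
    # near-identical streams: restrict the DP to a diagonal band; fall back
    # to the full DP when lengths diverge enough that the band could clip
    L <- ncol(prof); M <- length(seqi)
    band <- if (min(L, M) * 2 < max(L, M)) -1L
            else as.integer(max(64, 2 * abs(L - M) + 32))
    res <- gotoh_profile_align(prof, seqi, sim, p@gapOpen, p@gapExtend, band)
    ncolOut <- length(res$prof_idx)
    newProf <- matrix(0L, nrow(prof) + 1, ncolOut)
    hasP <- res$prof_idx > 0
    newProf[seq_len(nrow(prof)), hasP] <- prof[, res$prof_idx[hasP]]
    hasS <- res$seq_idx > 0
    newProf[nrow(prof) + 1, hasS] <- seqi[res$seq_idx[hasS]]
    prof <- newProf
    members <- c(members, i)
  }
  g <- gapChar()
  rowFromCodes <- function(codes) {
    paste(ifelse(codes > 0, alphabet[pmax(codes, 1)], g), collapse = "")
  }
  rows <- character(n)
  for (k in seq_along(members)) rows[members[k]] <- rowFromCodes(prof[k, ])
  new("MSAResult", rows = rows, streamIds = ids, seedIndex = as.integer(seed))
}

#' Call the consensus sequence from an alignment
#'
#' Per column, the plurality symbol among the row symbols is emitted (the gap
#' is a candidate: when it wins the column contributes nothing). Ties are
#' broken in favor of the seed stream's symbol, then lexicographically. The
#' per-character support is the fraction of rows voting for the emitted
#' symbol.
#'
#' @param msa an \linkS4class{MSAResult}
#' @return a \linkS4class{ConsensusText}
#' @export
callConsensus <- function(msa) {
  g <- gapChar()
  if (length(msa@rows) == 1) {
    txt <- msa@rows[1]
    return(new("ConsensusText", text = gsub(g, "", txt, fixed = TRUE),
               support = rep(1, nchar(gsub(g, "", txt, fixed = TRUE))),
               prunedStreamIds = character()))
  }
  rowsM <- do.call(rbind, strsplit(msa@rows, "", fixed = TRUE))
  nr <- nrow(rowsM)
  # integer encoding with the alphabet in codepoint order, so that code
  # order == lexicographic order (the gap sentinel sorts first)
  alphabet <- unique(as.vector(rowsM))
  alphabet <- alphabet[order(vapply(alphabet, function(ch) utf8ToInt(ch)[1],
                                    numeric(1)))]
  codes <- matrix(match(rowsM, alphabet), nrow = nr)
  A <- length(alphabet)
  picks <- integer(ncol(codes))
  supports <- numeric(ncol(codes))
  for (j in seq_len(ncol(codes))) {
    cnt <- tabulate(codes[, j], nbins = A)
    topN <- max(cnt)
    cand <- which(cnt == topN)
    pick <- if (length(cand) == 1) cand else {
      seedSym <- codes[msa@seedIndex, j]
      if (seedSym %in% cand) seedSym else cand[1]
    }
    picks[j] <- pick
    supports[j] <- topN / nr
  }
  emit <- alphabet[picks] != g
  new("ConsensusText", text = paste(alphabet[picks[emit]], collapse = ""),
      support = supports[emit], prunedStreamIds = character())
}
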