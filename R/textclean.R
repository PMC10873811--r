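#' @include consensus.R
NULL

#' A correction lexicon
#'
#' Accepted vocabulary (botanical, geographic, collector and general words)
#' used by \code{\link{postCleanup}}. Lookups are case-aware with a
#' case-folding fallback: a token is in-lexicon if it matches a term exactly
#' or after case folding both sides.
#'
#' @slot terms character vector of accepted words
#' @slot maxEdit correction radius in edit distance (default 1)
#' @export
setClass("Lexicon",
  representation(terms = "character", maxEdit = "integer"),
  validity = function(object) {
    if (length(object@terms) == 0) return("lexicon terms must be nonempty")
    if (object@maxEdit < 0) return("maxEdit must be >= 0")
    TRUE
  })

#' @param terms character vector of terms
#' @param maxEdit correction radius
#' @rdname Lexicon-class
#' @export
lexicon <- function(terms, maxEdit = 1L) {
  new("Lexicon", terms = unique(terms), maxEdit = as.integer(maxEdit))
}

setMethod("show", "Lexicon", function(object) {
  cat(sprintf("Lexicon: %d terms, correction radius %d\n",
              length(object@terms), object@maxEdit))
})

#' Load a lexicon from plain-text word lists
#'
#' Each file holds one term per line (UTF-8); the files are merged and
#' deduplicated. Mixed-case duplicates are both retained -- the case-folding
#' lookup finds either.
#'
#' @param paths character vector of file paths
#' @param maxEdit correction radius
#' @return a \linkS4class{Lexicon}
#' @export
loadLexicon <- function(paths, maxEdit = 1L) {
  if (length(paths) == 0)
    stop("no lexicon files given but spell correction is enabled")
  terms <- character()
  for (p in paths) {
    if (!file.exists(p)) stop("cannot read lexicon file: ", p)
    terms <- c(terms, readLines(p, encoding = "UTF-8", warn = FALSE))
  }
  terms <- unique(terms[nzchar(terms)])
  if (!length(terms))
    stop("merged lexicon is empty but spell correction is enabled")
  lexicon(terms, maxEdit)
}

inLexicon <- function(lex, token) {
  token %in% lex@terms || tolower(token) %in% tolower(lex@terms)
}

#' Default post-consensus substitution rules
#'
#' A documented starter set (the field's common-substitution lists are
#' neither extensive nor weighted): whitespace-before-punctuation fixes and a
#' couple of unambiguous glyph repairs. Columns: \code{pattern} (regex),
#' \code{replacement}, \code{scope} (\code{"text"} applies anywhere,
#' \code{"word"} wraps the pattern in word boundaries).
#'
#' @return data.frame of ordered rules
#' @export
defaultSubstitutionRules <- function() {
  data.frame(
    pattern = c("[ \t]+([.,;:])", "  +", "\\|"),
    replacement = c("\\1", " ", "l"),
    scope = c("text", "text", "text"),
    stringsAsFactors = FALSE)
}

# tokenization preserving separators: words = maximal runs of [A-Za-z0-9'],
# everything else (spaces, punctuation) is kept as separator tokens
.tokenize <- function(text) {
  if (!nchar(text)) return(data.frame(token = character(), word = logical()))
  cs <- chars(text)
  isw <- grepl("[A-Za-z0-9']", cs)
  runs <- rle(isw)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  data.frame(token = substring(text, starts, ends), word = runs$values,
             stringsAsFactors = FALSE)
}

#' Post-consensus text cleanup
#'
#' The final pipeline stage: applies the ordered substitution rules, repairs
#' words split by a spurious space (the two fragments are joined when the
#' join is in the lexicon and neither fragment is), and spell-corrects
#' out-of-lexicon word tokens that have exactly one lexicon neighbor within
#' the correction radius. Tokens with zero or several candidates are left
#' unchanged (abstention over hallucination -- the gold standard is verbatim),
#' as are tokens consisting only of digits (the lexicon cannot vouch for
#' dates, coordinates or collection numbers) and tokens of at most
#' \code{maxEdit + 1} characters, which a within-radius edit could rewrite
#' almost entirely. Every change is logged;
#' \code{\link{replayChanges}} reproduces the output from the input and the
#' log.
#'
#' @param text input text
#' @param rules substitution rules, see
#'   \code{\link{defaultSubstitutionRules}}
#' @param lex a \linkS4class{Lexicon}, or NULL to skip lexicon-based repair
#' @return list with \code{text} and \code{changes} (data.frame step, detail,
#'   before, after)
#' @examples
#' lx <- lexicon(c("Herbarium", "Texas"))
#' postCleanup("Herbar1um , Texas", lex = lx)$text
#' @export
postCleanup <- function(text, rules = defaultSubstitutionRules(), lex = NULL) {
  changes <- data.frame(step = character(), detail = character(),
                        before = character(), after = character(),
                        stringsAsFactors = FALSE)
  for (i in seq_len(nrow(rules))) {
    pat <- rules$pattern[i]
    if (identical(rules$scope[i], "word")) pat <- paste0("\\b", pat, "\\b")
    after <- gsub(pat, rules$replacement[i], text, perl = TRUE)
    if (!identical(after, text)) {
      changes <- rbind(changes, data.frame(
        step = "substitution", detail = pat, before = text, after = after))
      text <- after
    }
  }
  if (!is.null(lex)) {
    toks <- .tokenize(text)
    # join split words: word, single-space separator, word
    i <- 1L
    while (i <= nrow(toks) - 2L) {
      if (toks$word[i] && identical(toks$token[i + 1L], " ") &&
          isTRUE(toks$word[i + 2L])) {
        joined <- paste0(toks$token[i], toks$token[i + 2L])
        if (inLexicon(lex, joined) && !inLexicon(lex, toks$token[i]) &&
            !inLexicon(lex, toks$token[i + 2L])) {
          changes <- rbind(changes, data.frame(
            step = "join", detail = sprintf("tokens %d+%d", i, i + 2L),
            before = paste0(toks$token[i], " ", toks$token[i + 2L]),
            after = joined))
          toks <- rbind(
            if (i > 1) toks[seq_len(i - 1L), ] else NULL,
            data.frame(token = joined, word = TRUE),
            if (i + 3L <= nrow(toks)) toks[seq(i + 3L, nrow(toks)), ] else NULL)
        }
      }
      i <- i + 1L
    }
    # spell-correct word tokens
    for (i in seq_len(nrow(toks))) {
      tok <- toks$token[i]
      if (!toks$word[i] || !nzchar(tok)) next
      if (grepl("^[0-9]+$", tok)) next
      if (nchar(tok) <= lex@maxEdit + 1) next
      if (inLexicon(lex, tok)) next
      cand <- .spellCandidates(lex, tok)
      if (length(cand) == 1L) {
        changes <- rbind(changes, data.frame(
          step = "spell", detail = sprintf("token %d", i),
          before = tok, after = cand))
        toks$token[i] <- cand
      }
    }
    text <- paste(toks$token, collapse = "")
  }
  list(text = text, changes = changes)
}

# unique-neighbor lookup within the correction radius, length-pruned
.spellCandidates <- function(lex, token) {
  n <- nchar(token)
  pool <- lex@terms[abs(nchar(lex@terms) - n) <= lex@maxEdit]
  if (!length(pool)) return(character())
  d <- drop(adist(token, pool))
  hit <- pool[d <= lex@maxEdit]
  if (length(hit) > 1) {
    # distinct candidates that differ only by case count as one
    if (length(unique(tolower(hit))) == 1) hit <- hit[1]
  }
  hit
}

#' Replay a cleanup change log
#'
#' Applies the logged operations of \code{\link{postCleanup}} to the original
#' input, reproducing the output exactly.
#'
#' @param text the original input text
#' @param changes the change log returned by \code{\link{postCleanup}}
#' @return the cleaned text
#' @export
replayChanges <- function(text, changes) {
  toks <- NULL
  for (i in seq_len(nrow(changes))) {
    ch <- changes[i, ]
    if (ch$step == "substitution") {
      text <- ch$after
    } else {
      if (is.null(toks)) toks <- .tokenize(text)
      idx <- as.integer(regmatches(ch$detail,
                                   regexpr("[0-9]+", ch$detail)))
      if (ch$step == "join") {
        toks <- rbind(
          if (idx > 1) toks[seq_len(idx - 1L), ] else NULL,
          data.frame(token = ch$after, word = TRUE),
          if (idx + 3L <= nrow(toks)) toks[seq(idx + 3L, nrow(toks)), ]
          else NULL)
      } else {
        toks$token[idx] <- ch$after
      }
    }
  }
  if (!is.null(toks)) text <- paste(toks$token, collapse = "")
  text
}
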