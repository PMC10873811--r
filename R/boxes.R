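#' @include boxes-classes.R
NULL

#' Intersection over union of two bounding boxes
#'
#' The standard object-detection overlap metric: intersection area divided by
#' union area. 1 for identical boxes, 0 for disjoint ones; symmetric in its
#' arguments. Used both to score detector predictions against ground truth and
#' to flag outlier outlines during annotation reconciliation.
#'
#' @param a,b \linkS4class{BoundingBox} objects
#' @return a ratio in \code{[0, 1]}
#' @examples
#' iou(boundingBox(0, 0, 10, 10), boundingBox(5, 0, 15, 10))  # 1/3
#' @export
iou <- function(a, b) {
  validObject(a); validObject(b)
  ix <- min(a@xMax, b@xMax) - max(a@xMin, b@xMin)
  iy <- min(a@yMax, b@yMax) - max(a@yMin, b@yMin)
  inter <- max(0, ix) * max(0, iy)
  un <- boxArea(a) + boxArea(b) - inter
  inter / un
}

#' Reconcile several participant outlines of one label
#'
#' Each image receives independent outlines (three, at the usual retirement
#' limit) of every label. Outlines "very different from the others" are
#' trimmed iteratively: while any outline's mean IoU against the current
#' others is below \code{outlierIoU}, the worst one is removed and the means
#' are recomputed (one bad outline cannot drag its agreeing peers below the
#' bar). If trimming would leave fewer than two mutually consistent
#' outlines, the set is mutually outlying and an error routes the label to
#' human review. The survivors are averaged corner-wise (arithmetic mean of
#' each of the four coordinates) and the label type is the strict majority
#' vote among the surviving annotations, else \code{"unresolved"} for a
#' human to settle.
#'
#' @param outlines list of \linkS4class{LabelAnnotation}s for one physical label
#' @param outlierIoU mean-IoU-vs-remaining-others threshold below which an
#'   outline is an outlier (strict \code{<}; default 0.5)
#' @return a \linkS4class{ReconciledLabel}
#' @examples
#' a <- labelAnnotation(boundingBox(0, 0, 10, 10), "typewritten", "p1")
#' b <- labelAnnotation(boundingBox(0, 0, 10, 10), "typewritten", "p2")
#' c <- labelAnnotation(boundingBox(500, 500, 510, 510), "handwritten", "p3")
#' reconcileAnnotations(list(a, b, c))
#' @export
reconcileAnnotations <- function(outlines, outlierIoU = 0.5) {
  if (length(outlines) == 0) stop("reconcileAnnotations: empty outline list")
  stopifnot(all(vapply(outlines, is, TRUE, class2 = "LabelAnnotation")))
  n <- length(outlines)
  keep <- rep(TRUE, n)
  if (n >= 2) {
    m <- matrix(0, n, n)
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      m[i, j] <- m[j, i] <- iou(outlines[[i]]@box, outlines[[j]]@box)
    }
    repeat {
      idx <- which(keep)
      meanOthers <- rowSums(m[idx, idx, drop = FALSE]) / (length(idx) - 1)
      bad <- meanOthers < outlierIoU
      if (!any(bad)) break
      if (length(idx) <= 2)
        stop("reconcileAnnotations: all outlines are mutual outliers; ",
             "route this label to human review")
      worst <- idx[order(meanOthers, rowSums(m[idx, idx, drop = FALSE]))[1]]
      keep[worst] <- FALSE
    }
  }
  kept <- outlines[keep]
  co <- vapply(kept, function(a) boxCoords(a@box), numeric(4))
  avg <- rowMeans(co)
  types <- vapply(kept, function(a) a@labelType, character(1))
  tab <- sort(table(types), decreasing = TRUE)
  majority <- names(tab)[1]
  resolved <- tab[1] * 2 > length(types)   # strict majority
  new("ReconciledLabel",
      box = boundingBox(avg["xMin"], avg["yMin"], avg["xMax"], avg["yMax"]),
      labelType = if (resolved) majority else "unresolved",
      nContributing = as.integer(length(kept)),
      outliersRemoved = as.integer(n - length(kept)),
      resolved = resolved)
}

#' Drop correction clicks that fall outside every known label
#'
#' Correction-expedition participants occasionally click outside any label; a
#' cleaning pass removes those. A click on a box boundary counts as inside.
#' Retained clicks are tagged with the index of the containing label
#' (smallest-area box when several contain the point).
#'
#' @param clicks list of \linkS4class{CorrectionClick}s
#' @param labels list of \linkS4class{ReconciledLabel}s on the same sheet
#' @return the retained clicks, each with a \code{labelIndex} attribute; the
#'   list carries no other changes, so the output is always a subset of the
#'   input and the operation is idempotent
#' @export
cleanCorrectionClicks <- function(clicks, labels) {
  if (length(clicks) == 0 || length(labels) == 0) return(list())
  areas <- vapply(labels, function(l) boxArea(l@box), numeric(1))
  out <- list()
  for (cl in clicks) {
    inside <- vapply(labels, function(l) {
      b <- l@box
      cl@x >= b@xMin && cl@x <= b@xMax && cl@y >= b@yMin && cl@y <= b@yMax
    }, logical(1))
    if (any(inside)) {
      idx <- which(inside)[which.min(areas[inside])]
      attr(cl, "labelIndex") <- idx
      out[[length(out) + 1L]] <- cl
    }
  }
  out
}

#' Score predicted label boxes against ground truth
#'
#' Greedy one-to-one matching in descending IoU order (ties broken by
#' prediction order, then truth order); only overlapping pairs (IoU > 0) can
#' match. The mean IoU over matched pairs is the detection success metric;
#' unmatched predictions are reported as phantom labels and unmatched truths
#' as misses.
#'
#' @param preds,truths lists of \linkS4class{LabelAnnotation}s
#' @return list with \code{meanIoU} (NA when nothing matched), \code{matches}
#'   (data.frame pred, truth, iou), \code{phantoms} and \code{misses}
#'   (indices of unmatched predictions / truths)
#' @export
scorePredictions <- function(preds, truths) {
  np <- length(preds); nt <- length(truths)
  pairs <- data.frame(pred = integer(), truth = integer(), iou = numeric())
  if (np > 0 && nt > 0) {
    g <- expand.grid(pred = seq_len(np), truth = seq_len(nt))
    g$iou <- mapply(function(i, j) iou(preds[[i]]@box, truths[[j]]@box),
                    g$pred, g$truth)
    g <- g[g$iou > 0, , drop = FALSE]
    g <- g[order(-g$iou, g$pred, g$truth), , drop = FALSE]
    usedP <- logical(np); usedT <- logical(nt)
    for (r in seq_len(nrow(g))) {
      i <- g$pred[r]; j <- g$truth[r]
      if (!usedP[i] && !usedT[j]) {
        usedP[i] <- TRUE; usedT[j] <- TRUE
        pairs <- rbind(pairs, g[r, ])
      }
    }
  } else {
    usedP <- logical(np); usedT <- logical(nt)
  }
  list(meanIoU = if (nrow(pairs)) mean(pairs$iou) else NA_real_,
       matches = pairs[order(pairs$pred), , drop = FALSE],
       phantoms = which(!usedP),
       misses = which(!usedT))
}

#' Read and write label-record JSON
#'
#' The interchange schema of the label-finder service: per sheet, a list of
#' objects with the label type, pixel bounding box, optional transcription for
#' typewritten labels, and provenance.
#'
#' @param sheetId sheet identifier
#' @param labels list of \linkS4class{ReconciledLabel} or
#'   \linkS4class{LabelAnnotation} objects
#' @param texts optional named character vector/list mapping label index (as
#'   character) to transcribed text; only typewritten labels carry text
#' @param provenance optional list recorded per document
#' @param path optional file to write to
#' @return the JSON string (invisibly when written to \code{path})
#' @export
exportLabelsJSON <- function(sheetId, labels, texts = NULL, provenance = list(),
                             path = NULL) {
  recs <- lapply(seq_along(labels), function(i) {
    l <- labels[[i]]
    b <- if (is(l, "ReconciledLabel") || is(l, "LabelAnnotation")) l@box else l
    type <- if (is(l, "BoundingBox")) "other" else l@labelType
    rec <- list(type = type,
                bbox = unname(boxCoords(b)))
    if (is(l, "LabelAnnotation")) rec$source <- l@sourceId
    key <- as.character(i)
    if (type == "typewritten" && !is.null(texts) && !is.null(texts[[key]]))
      rec$text <- texts[[key]]
    rec
  })
  doc <- list(sheet = sheetId, labels = recs)
  if (length(provenance)) doc$provenance <- provenance
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(as.character(js)))
  }
  as.character(js)
}

#' @rdname exportLabelsJSON
#' @param json a JSON string or path to a JSON file
#' @return \code{readLabelsJSON}: list with \code{sheet}, \code{labels} (list
#'   of lists with \code{type}, \code{box}, optional \code{text}, \code{source})
#' @export
readLabelsJSON <- function(json) {
  doc <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  labels <- lapply(doc$labels, function(r) {
    b <- as.numeric(unlist(r$bbox))
    out <- list(type = r$type, box = boundingBox(b[1], b[2], b[3], b[4]))
    if (!is.null(r$text)) out$text <- r$text
    if (!is.null(r$source)) out$source <- r$source
    out
  })
  list(sheet = doc$sheet, labels = labels, provenance = doc$provenance)
}
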