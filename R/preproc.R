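#' @include preproc-classes.R
NULL

#' Read an image file as a grayscale LabelImage
#'
#' PNG, JPEG and TIFF are supported. Color images are converted to luminance
#' with the standard Rec. 601 weights (0.299 R + 0.587 G + 0.114 B) and scaled
#' to the 0--255 range.
#'
#' @param path image file
#' @return a \linkS4class{LabelImage}
#' @export
readLabelImage <- function(path) {
  im <- EBImage::readImage(path)
  d <- EBImage::imageData(im)
  if (length(dim(d)) == 3) {
    nch <- dim(d)[3]
    if (nch >= 3) {
      d <- 0.299 * d[, , 1] + 0.587 * d[, , 2] + 0.114 * d[, , 3]
    } else {
      d <- d[, , 1]
    }
  }
  px <- t(d) * 255
  px[px < 0] <- 0; px[px > 255] <- 255
  img <- labelImage(px)
  withStep(img, px, "read", list(path = basename(path)))
}

#' Write a LabelImage, optionally with a provenance sidecar
#'
#' @param img a \linkS4class{LabelImage}
#' @param path output image path (format from extension; PNG/TIFF/JPEG)
#' @param sidecar if TRUE, also write \code{<path>.json} listing every
#'   transform applied and its parameters
#' @return invisibly, \code{path}
#' @export
writeLabelImage <- function(img, path, sidecar = FALSE) {
  px <- if (img@binary) 1 - img@pixels else img@pixels / 255
  EBImage::writeImage(EBImage::Image(t(px)), path)
  if (sidecar) {
    writeLines(jsonlite::toJSON(
      list(variant = img@variantApplied, provenance = img@provenance),
      auto_unbox = TRUE, digits = NA, null = "null"), paste0(path, ".json"))
  }
  invisible(path)
}

# internal: foreground (ink) mask as 0/1 matrix
inkMask <- function(img) {
  if (img@binary) return(img@pixels)
  p <- img@pixels
  thr <- (max(p) + min(p)) / 2
  if (max(p) == min(p)) return(matrix(0, nrow(p), ncol(p)))
  (p < thr) * 1
}

# exact multiples-of-90 rotations on a matrix (clockwise)
rot90cw <- function(m) t(m[nrow(m):1, , drop = FALSE])
rotMat <- function(m, deg) {
  deg <- deg %% 360
  if (deg == 0) return(m)
  for (i in seq_len(deg / 90)) m <- rot90cw(m)
  m
}

#' Gaussian blur and isotropic rescale
#'
#' The first steps of the V2 chain: a slight blur suppresses scanner noise
#' and the rescale brings the label to a size OCR engines handle well. The
#' aspect ratio is preserved; the longer side is scaled to
#' \code{targetLongSide}.
#'
#' @param img grayscale \linkS4class{LabelImage}
#' @param blurRadius Gaussian sigma in pixels; 0 skips the blur
#' @param targetLongSide target length of the longer side; NULL or equal to
#'   the current long side skips the rescale
#' @return a \linkS4class{LabelImage}
#' @export
blurScale <- function(img, blurRadius = 0.5, targetLongSide = 4096) {
  stopifnot(blurRadius >= 0)
  px <- img@pixels
  if (blurRadius > 0) {
    im <- EBImage::gblur(EBImage::Image(t(px) / 255), sigma = blurRadius)
    px <- t(EBImage::imageData(im)) * 255
    px[px < 0] <- 0; px[px > 255] <- 255
  }
  if (!is.null(targetLongSide)) {
    stopifnot(targetLongSide > 0)
    long <- max(dim(px))
    if (long != targetLongSide) {
      f <- targetLongSide / long
      neww <- if (ncol(px) >= nrow(px)) targetLongSide else max(1L, round(ncol(px) * f))
      newh <- if (nrow(px) > ncol(px)) targetLongSide else max(1L, round(nrow(px) * f))
      im <- EBImage::resize(EBImage::Image(t(px) / 255), w = neww, h = newh)
      px <- t(EBImage::imageData(im)) * 255
      px[px < 0] <- 0; px[px > 255] <- 255
    }
  }
  withStep(img, px, "blur_scale",
           list(blurRadius = blurRadius, targetLongSide = targetLongSide))
}

# Baseline-asymmetry statistic: the mean skewness of the per-line row
# profiles, mapped to (0, 1). Upright Latin text piles its ink into the
# x-height band just above the baseline, with a long sparse tail upward into
# the ascender/capital zone and a short one downward (descenders are rare),
# so the profile skews toward the top (negative third moment). Upside-down
# text mirrors the sign. All-capital lines are nearly symmetric and
# contribute ~0, which is what makes them genuinely ambiguous.
.uprightness <- function(mask) {
  rs <- rowSums(mask)
  on <- rs > 0
  if (!any(on)) return(NA_real_)
  runs <- rle(on)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  sk <- c()
  for (k in which(runs$values)) {
    a <- starts[k]; b <- ends[k]
    h <- b - a + 1
    if (h < 3) next
    w <- rs[a:b]
    r <- seq_len(h)
    cen <- sum(r * w) / sum(w)
    s <- sqrt(sum(w * (r - cen)^2) / sum(w))
    if (s > 0) sk <- c(sk, sum(w * ((r - cen) / s)^3) / sum(w))
  }
  if (!length(sk)) return(NA_real_)
  1 / (1 + exp(3 * mean(sk)))   # negative skew (upright) -> > 0.5
}

#' Rotate a label image upright
#'
#' Chooses the rotation in \{0, 90, 180, 270\} degrees that maximizes a
#' projection-profile orientation score: the variance of the row-sum profile
#' (text lines are horizontal bands, so the profile of an upright or
#' upside-down page is far spikier than a sideways one) weighted by a
#' baseline-asymmetry statistic (ink in Latin text sits low within each line's
#' vertical extent, which distinguishes upright from upside-down). A blank
#' image, or a near-tie between candidate rotations, is flagged low
#' confidence.
#'
#' @param img a \linkS4class{LabelImage} containing text-like foreground
#' @return list with \code{image} (rotated \linkS4class{LabelImage}),
#'   \code{rotation} (degrees applied, multiple of 90) and
#'   \code{lowConfidence} (logical)
#' @export
orientUpright <- function(img) {
  mask <- inkMask(img)
  if (sum(mask) == 0) {
    out <- withStep(img, img@pixels, "orient",
                    list(rotation = 0, lowConfidence = TRUE))
    return(list(image = out, rotation = 0L, lowConfidence = TRUE))
  }
  rots <- c(0L, 90L, 180L, 270L)
  scores <- vapply(rots, function(r) {
    m <- rotMat(mask, r)
    lineVar <- var(rowSums(m))
    u <- .uprightness(m)
    if (is.na(u)) u <- 0.5
    lineVar * u
  }, numeric(1))
  best <- rots[which.max(scores)]
  srt <- sort(scores, decreasing = TRUE)
  low <- srt[1] <= 0 || (srt[2] / srt[1]) > 0.98
  px <- rotMat(img@pixels, best)
  out <- withStep(img, px, "orient", list(rotation = best, lowConfidence = low))
  list(image = out, rotation = best, lowConfidence = low)
}

# vertical shear: shift column x down by round(tan(angle) * (x - centre)),
# expanding the canvas as needed. First-order equivalent to rotation for the
# small angles deskewing deals with, and the exact inverse of the renderer's
# skew model.
shearImage <- function(px, angleDeg, bg) {
  if (angleDeg == 0) return(px)
  nc <- ncol(px); nr <- nrow(px)
  cx <- (nc + 1) / 2
  shift <- round(tan(angleDeg * pi / 180) * (seq_len(nc) - cx))
  lo <- min(shift); hi <- max(shift)
  out <- matrix(bg, nr + hi - lo, nc)
  for (x in seq_len(nc)) {
    off <- shift[x] - lo
    out[seq_len(nr) + off, x] <- px[, x]
  }
  out
}

#' Estimate and remove small-angle text skew
#'
#' Searches a grid of candidate angles for the one maximizing the variance of
#' the sheared row-projection profile -- the classic projection-profile skew
#' estimator for documents. The image is then corrected by the negative of
#' the estimate (applied as a vertical shear, which equals a rotation to first
#' order at these angles).
#'
#' @param img a \linkS4class{LabelImage}
#' @param maxAngle search half-range in degrees
#' @param step grid step in degrees
#' @return list with \code{image} (corrected \linkS4class{LabelImage}) and
#'   \code{angle} (estimated skew, degrees; positive = text lines rising to
#'   the right)
#' @export
deskew <- function(img, maxAngle = 10, step = 0.1) {
  mask <- inkMask(img)
  idx <- which(mask == 1, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    out <- withStep(img, img@pixels, "deskew", list(angle = 0))
    return(list(image = out, angle = 0))
  }
  if (nrow(idx) > 20000) {
    sel <- round(seq(1, nrow(idx), length.out = 20000))
    idx <- idx[sel, , drop = FALSE]
  }
  r <- idx[, 1]; cc <- idx[, 2] - (ncol(mask) + 1) / 2
  angles <- seq(-maxAngle, maxAngle, by = step)
  scores <- vapply(angles, function(t) {
    y <- round(r + tan(t * pi / 180) * cc)
    counts <- tabulate(y - min(y) + 1L)
    var(counts)
  }, numeric(1))
  best <- max(scores)
  cand <- angles[scores == best]
  angle <- cand[which.min(abs(cand))]
  bg <- if (img@binary) 0 else 255
  px <- shearImage(img@pixels, angle, bg)
  out <- withStep(img, px, "deskew", list(angle = angle))
  list(image = out, angle = angle)
}

#' Sauvola adaptive binarization
#'
#' Thresholds each pixel against \code{T = m * (1 + k * (s / R - 1))}, where
#' \code{m} and \code{s} are the mean and standard deviation of the intensities
#' in the local window centred on the pixel (clamped to the image at the
#' borders). A pixel becomes foreground (ink) iff its intensity is strictly
#' below its local threshold. Robust on degraded documents where a single
#' global threshold fails.
#'
#' @param img grayscale \linkS4class{LabelImage}
#' @param window odd window size >= 3
#' @param k sensitivity, in (0, 1)
#' @param R dynamic range of the standard deviation
#' @return a binary \linkS4class{LabelImage} (1 = ink)
#' @export
sauvolaBinarize <- function(img, window = 31, k = 0.2, R = 128) {
  if (img@binary) stop("sauvolaBinarize expects a grayscale image")
  stopifnot(window >= 3, window %% 2 == 1, k > 0, k < 1, R > 0)
  p <- img@pixels
  nr <- nrow(p); nc <- ncol(p)
  if (window > nr || window > nc) {
    warning("Sauvola window larger than image; clamping to image size")
  }
  half <- (window - 1) / 2
  S1 <- matrix(0, nr + 1, nc + 1)
  S2 <- matrix(0, nr + 1, nc + 1)
  S1[-1, -1] <- apply(apply(p, 2, cumsum), 1, cumsum) |> t()
  S2[-1, -1] <- apply(apply(p^2, 2, cumsum), 1, cumsum) |> t()
  r1 <- pmax(1, seq_len(nr) - half); r2 <- pmin(nr, seq_len(nr) + half)
  c1 <- pmax(1, seq_len(nc) - half); c2 <- pmin(nc, seq_len(nc) + half)
  wsum <- S1[r2 + 1, c2 + 1] - S1[r1, c2 + 1] - S1[r2 + 1, c1] + S1[r1, c1]
  wsq  <- S2[r2 + 1, c2 + 1] - S2[r1, c2 + 1] - S2[r2 + 1, c1] + S2[r1, c1]
  n <- outer(r2 - r1 + 1, c2 - c1 + 1)
  m <- wsum / n
  s <- sqrt(pmax(0, wsq / n - m^2))
  thr <- m * (1 + k * (s / R - 1))
  fg <- (p < thr) * 1
  withStep(img, fg, "sauvola", list(window = window, k = k, R = R),
           binary = TRUE)
}

#' Remove speckles and fill small holes in a binary image
#'
#' "Snow" -- isolated foreground components smaller than \code{minSpeck}
#' pixels -- is deleted, and enclosed background components (holes) smaller
#' than \code{minHole} pixels are filled. Foreground uses 8-connectivity,
#' background 4-connectivity, the usual dual pairing. Idempotent.
#'
#' @param img binary \linkS4class{LabelImage}
#' @param minSpeck minimum surviving foreground component area, pixels
#' @param minHole holes strictly smaller than this are filled
#' @return a binary \linkS4class{LabelImage}
#' @export
despeckleFill <- function(img, minSpeck = 4, minHole = 4) {
  if (!img@binary) stop("despeckleFill expects a binary image")
  p <- img@pixels
  mode(p) <- "integer"
  lab <- cc_label_cpp(p, 8L)
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0])
    drop <- which(areas < minSpeck)
    if (length(drop)) p[lab %in% drop] <- 0L
  }
  bg <- 1L - p
  lab <- cc_label_cpp(bg, 4L)
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0])
    border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    fill <- setdiff(which(areas < minHole), border)
    if (length(fill)) p[lab %in% fill] <- 1L
  }
  storage.mode(p) <- "double"
  withStep(img, p, "despeckle_fill",
           list(minSpeck = minSpeck, minHole = minHole), binary = TRUE)
}

#' Apply one of the four pre-processing variants
#'
#' The variants are cumulative: V1 passes the image through untouched (OCR on
#' the raw label sometimes works best on recent sheets); V2 blurs slightly,
#' rescales, rotates upright and deskews; V3 runs all V2 steps and then
#' Sauvola-binarizes; V4 runs all V3 steps and then despeckles and fills
#' holes.
#'
#' @param img grayscale \linkS4class{LabelImage}
#' @param variant one of \code{preprocVariants} (short forms "V1".."V4"
#'   accepted)
#' @param params a \code{\link{preprocParams}} list
#' @return a \linkS4class{LabelImage} with \code{variantApplied} set
#' @export
applyVariant <- function(img, variant, params = preprocParams()) {
  v <- match(variant, preprocVariants)
  if (is.na(v)) v <- match(variant, c("V1", "V2", "V3", "V4"))
  if (is.na(v)) stop("unknown pre-processing variant: ", variant)
  vid <- preprocVariants[v]
  if (v == 1) {
    out <- withStep(img, img@pixels, "variant_V1", variant = vid)
    return(out)
  }
  out <- blurScale(img, params$blurRadius, params$targetLongSide)
  out <- orientUpright(out)$image
  out <- deskew(out, params$maxSkew, params$skewStep)$image
  if (v >= 3) out <- sauvolaBinarize(out, params$sauvolaWindow,
                                     params$sauvolaK, params$sauvolaR)
  if (v >= 4) out <- despeckleFill(out, params$minSpeck, params$minHole)
  out@variantApplied <- vid
  validObject(out)
  out
}
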