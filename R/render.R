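#' @include font.R engines-classes.R
NULL

#' Style parameters for the synthetic label renderer
#'
#' @param scale integer pixel magnification of the base typeface
#' @param skew skew angle in degrees (positive = text lines rising to the
#'   right)
#' @param speckleDensity expected isolated one-pixel specks per image pixel
#' @param margin blank margin around the text block, in base-font pixels
#' @return named list of style parameters
#' @export
labelStyle <- function(scale = 2L, skew = 0, speckleDensity = 0, margin = 6L) {
  list(scale = as.integer(scale), skew = skew,
       speckleDensity = speckleDensity, margin = as.integer(margin))
}

#' Render a synthetic typewritten label image
#'
#' Rasterizes the text with the package's built-in bitmap typeface, applies a
#' known skew and sprinkles isolated one-pixel specks ("snow"), returning the
#' image together with its ground truth (text, skew angle, speck count) in
#' the metadata for oracle use in tests. Newlines break lines. Deterministic
#' given the seed.
#'
#' @param text text to render; every character must be in
#'   \code{\link{printableChars}} (or a newline)
#' @param style a \code{\link{labelStyle}} list
#' @param seed integer seed for the speckle placement
#' @param labelId identifier stored in the metadata
#' @return a grayscale \linkS4class{LabelImage}; metadata fields
#'   \code{truthText}, \code{skew}, \code{speckleCount}, \code{labelId}
#' @export
renderLabel <- function(text, style = labelStyle(), seed = 1L,
                        labelId = "label") {
  glyphs <- fontGlyphs()
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (length(lines) == 0) lines <- ""
  bad <- setdiff(unique(chars(gsub("\n", "", text, fixed = TRUE))),
                 names(glyphs))
  if (length(bad))
    stop("unprintable character(s) for the built-in typeface: ",
         paste(sQuote(bad), collapse = ", "))
  ncols <- max(1L, max(nchar(lines))) * .FONT_ADV
  nrows <- length(lines) * (.FONT_H + .FONT_LEAD)
  ink <- matrix(0L, nrows, ncols)
  for (li in seq_along(lines)) {
    cs <- if (nchar(lines[li])) chars(lines[li]) else character()
    r0 <- (li - 1L) * (.FONT_H + .FONT_LEAD)
    for (ci in seq_along(cs)) {
      g <- glyphs[[cs[ci]]]
      c0 <- (ci - 1L) * .FONT_ADV
      ink[r0 + seq_len(.FONT_H), c0 + seq_len(.FONT_W)] <- g
    }
  }
  s <- style$scale
  if (s > 1) ink <- ink[rep(seq_len(nrow(ink)), each = s),
                        rep(seq_len(ncol(ink)), each = s)]
  m <- style$margin * s
  canvas <- matrix(0L, nrow(ink) + 2 * m, ncol(ink) + 2 * m)
  canvas[m + seq_len(nrow(ink)), m + seq_len(ncol(ink))] <- ink
  if (style$skew != 0) {
    # renderer skew: column x rises by tan(skew) * (x - centre)
    canvas <- shearImage(canvas, -style$skew, 0L)
  }
  nspeck <- 0L
  if (style$speckleDensity > 0) {
    canvas <- withSeed(seed, {
      target <- round(style$speckleDensity * length(canvas))
      pos <- sample(length(canvas), min(target, length(canvas)))
      nr <- nrow(canvas)
      for (p in pos) {
        r <- ((p - 1) %% nr) + 1
        cc <- ((p - 1) %/% nr) + 1
        rs <- max(1, r - 1):min(nr, r + 1)
        cc2 <- max(1, cc - 1):min(ncol(canvas), cc + 1)
        if (sum(canvas[rs, cc2]) == 0) {
          canvas[r, cc] <- 1L
          nspeck <- nspeck + 1L
        }
      }
      canvas
    })
  }
  px <- 255 * (1 - canvas)
  img <- labelImage(px, metadata = list(truthText = text, skew = style$skew,
                                        speckleCount = nspeck,
                                        labelId = labelId))
  withStep(img, px, "render",
           list(style = style, seed = as.integer(seed)))
}
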