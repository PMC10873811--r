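#' @include AllGenerics.R
NULL

## A small built-in bitmap typeface (synthetic; no system fonts involved) so
## that rendered fixtures are bit-identical across machines. Capitals and
## digits occupy a 5x7 cell above the baseline; lowercase letters are derived
## from the capital shapes: plain letters are squashed into the x-height zone,
## ascender letters (b d f h k l t) keep the full cap height, and descender
## letters (g j p q y) hang two rows below the baseline. The asymmetric
## vertical ink distribution this produces is what the page-orientation
## heuristic keys on, as it does for real Latin text.

.glyph <- function(...) {
  rows <- c(...)
  m <- do.call(rbind, lapply(rows, function(r)
    as.integer(chars(r) == "#")))
  m
}

.fontBase <- function() {
  g <- list()
  g[["A"]] <- .glyph(".###.", "#...#", "#...#", "#####", "#...#", "#...#", "#...#")
  g[["B"]] <- .glyph("####.", "#...#", "#...#", "####.", "#...#", "#...#", "####.")
  g[["C"]] <- .glyph(".###.", "#...#", "#....", "#....", "#....", "#...#", ".###.")
  g[["D"]] <- .glyph("####.", "#...#", "#...#", "#...#", "#...#", "#...#", "####.")
  g[["E"]] <- .glyph("#####", "#....", "#....", "####.", "#....", "#....", "#####")
  g[["F"]] <- .glyph("#####", "#....", "#....", "####.", "#....", "#....", "#....")
  g[["G"]] <- .glyph(".###.", "#...#", "#....", "#.###", "#...#", "#...#", ".####")
  g[["H"]] <- .glyph("#...#", "#...#", "#...#", "#####", "#...#", "#...#", "#...#")
  g[["I"]] <- .glyph(".###.", "..#..", "..#..", "..#..", "..#..", "..#..", ".###.")
  g[["J"]] <- .glyph("..###", "...#.", "...#.", "...#.", "...#.", "#..#.", ".##..")
  g[["K"]] <- .glyph("#...#", "#..#.", "#.#..", "##...", "#.#..", "#..#.", "#...#")
  g[["L"]] <- .glyph("#....", "#....", "#....", "#....", "#....", "#....", "#####")
  g[["M"]] <- .glyph("#...#", "##.##", "#.#.#", "#.#.#", "#...#", "#...#", "#...#")
  g[["N"]] <- .glyph("#...#", "##..#", "#.#.#", "#..##", "#...#", "#...#", "#...#")
  g[["O"]] <- .glyph(".###.", "#...#", "#...#", "#...#", "#...#", "#...#", ".###.")
  g[["P"]] <- .glyph("####.", "#...#", "#...#", "####.", "#....", "#....", "#....")
  g[["Q"]] <- .glyph(".###.", "#...#", "#...#", "#...#", "#.#.#", "#..#.", ".##.#")
  g[["R"]] <- .glyph("####.", "#...#", "#...#", "####.", "#.#..", "#..#.", "#...#")
  g[["S"]] <- .glyph(".####", "#....", "#....", ".###.", "....#", "....#", "####.")
  g[["T"]] <- .glyph("#####", "..#..", "..#..", "..#..", "..#..", "..#..", "..#..")
  g[["U"]] <- .glyph("#...#", "#...#", "#...#", "#...#", "#...#", "#...#", ".###.")
  g[["V"]] <- .glyph("#...#", "#...#", "#...#", "#...#", "#...#", ".#.#.", "..#..")
  g[["W"]] <- .glyph("#...#", "#...#", "#...#", "#.#.#", "#.#.#", "##.##", "#...#")
  g[["X"]] <- .glyph("#...#", "#...#", ".#.#.", "..#..", ".#.#.", "#...#", "#...#")
  g[["Y"]] <- .glyph("#...#", "#...#", ".#.#.", "..#..", "..#..", "..#..", "..#..")
  g[["Z"]] <- .glyph("#####", "....#", "...#.", "..#..", ".#...", "#....", "#####")
  g[["0"]] <- .glyph(".###.", "#...#", "#..##", "#.#.#", "##..#", "#...#", ".###.")
  g[["1"]] <- .glyph("..#..", ".##..", "..#..", "..#..", "..#..", "..#..", ".###.")
  g[["2"]] <- .glyph(".###.", "#...#", "....#", "..##.", ".#...", "#....", "#####")
  g[["3"]] <- .glyph(".###.", "#...#", "....#", "..##.", "....#", "#...#", ".###.")
  g[["4"]] <- .glyph("...#.", "..##.", ".#.#.", "#..#.", "#####", "...#.", "...#.")
  g[["5"]] <- .glyph("#####", "#....", "####.", "....#", "....#", "#...#", "####.")
  g[["6"]] <- .glyph(".###.", "#....", "#....", "####.", "#...#", "#...#", ".###.")
  g[["7"]] <- .glyph("#####", "....#", "...#.", "..#..", ".#...", ".#...", ".#...")
  g[["8"]] <- .glyph(".###.", "#...#", "#...#", ".###.", "#...#", "#...#", ".###.")
  g[["9"]] <- .glyph(".###.", "#...#", "#...#", ".####", "....#", "....#", ".###.")
  g[["."]] <- .glyph(".....", ".....", ".....", ".....", ".....", ".##..", ".##..")
  g[[","]] <- .glyph(".....", ".....", ".....", ".....", "..##.", "..##.", "..#..")
  g[["-"]] <- .glyph(".....", ".....", ".....", ".###.", ".....", ".....", ".....")
  g[[":"]] <- .glyph(".....", ".##..", ".##..", ".....", ".##..", ".##..", ".....")
  g[[";"]] <- .glyph(".....", ".##..", ".##..", ".....", ".##..", ".#...", ".....")
  g[["("]] <- .glyph("...#.", "..#..", ".#...", ".#...", ".#...", "..#..", "...#.")
  g[[")"]] <- .glyph(".#...", "..#..", "...#.", "...#.", "...#.", "..#..", ".#...")
  g[["/"]] <- .glyph("....#", "...#.", "...#.", "..#..", ".#...", ".#...", "#....")
  g[["&"]] <- .glyph(".##..", "#..#.", "#.#..", ".#...", "#.#.#", "#..#.", ".##.#")
  g[["'"]] <- .glyph("..#..", "..#..", ".....", ".....", ".....", ".....", ".....")
  g[["|"]] <- .glyph("..#..", "..#..", "..#..", "..#..", "..#..", "..#..", "..#..")
  g
}

# cell geometry: 9 rows tall (7 above-baseline + 2 descender), 5 wide
.FONT_ASC <- 7L
.FONT_DESC <- 2L
.FONT_H <- .FONT_ASC + .FONT_DESC
.FONT_W <- 5L
.FONT_ADV <- 6L      # advance: glyph + 1 blank column
.FONT_LEAD <- 3L     # blank rows between lines

.fontCache <- new.env(parent = emptyenv())

# full glyph set placed in the 9-row cell
fontGlyphs <- function() {
  if (!is.null(.fontCache$glyphs)) return(.fontCache$glyphs)
  base <- .fontBase()
  place <- function(m7, top) {
    cell <- matrix(0L, .FONT_H, .FONT_W)
    cell[seq(top, top + nrow(m7) - 1L), ] <- m7
    cell
  }
  out <- list()
  for (nm in names(base)) out[[nm]] <- place(base[[nm]], 1L)
  squash <- function(m7) m7[c(1L, 3L, 4L, 5L, 7L), , drop = FALSE]  # 5-row x-height form
  asc <- c("b", "d", "f", "h", "k", "l", "t")
  desc <- c("g", "j", "p", "q", "y")
  for (up in LETTERS) {
    lo <- tolower(up)
    if (lo %in% asc) {
      out[[lo]] <- place(base[[up]], 1L)
    } else if (lo %in% desc) {
      out[[lo]] <- place(base[[up]], 3L)
    } else {
      cell <- matrix(0L, .FONT_H, .FONT_W)
      cell[3:7, ] <- squash(base[[up]])
      out[[lo]] <- cell
    }
  }
  out[[" "]] <- matrix(0L, .FONT_H, .FONT_W)
  .fontCache$glyphs <- out
  out
}

#' Characters the synthetic renderer can draw
#'
#' @return character vector of printable glyphs (includes the space)
#' @export
printableChars <- function() names(fontGlyphs())
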