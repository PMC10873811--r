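# Independent oracles used across the suite. These are deliberately naive
# reimplementations from first principles, kept apart from the package's own
# code paths.

# Levenshtein: full DP matrix, textbook recurrence
levOracle <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  D <- matrix(0L, n + 1, m + 1)
  D[, 1] <- 0:n
  D[1, ] <- 0:m
  for (i in seq_len(n)) for (j in seq_len(m)) {
    D[i + 1, j + 1] <- min(D[i, j] + (ca[i] != cb[j]),
                           D[i, j + 1] + 1L,
                           D[i + 1, j] + 1L)
  }
  D[n + 1, m + 1]
}

# Optimal global alignment score under affine gaps, by memoized recursion
# over (i, j, previous-move) -- the maximum over every possible alignment.
# Validated below (in the tests) against alignEnumAll, a true brute-force
# enumeration of all alignments, on tiny instances.
alignOracle <- function(a, b, scoreFn, gapOpen, gapExtend) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j, prev) {
    key <- paste(i, j, prev)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m) {
      best <- max(best, scoreFn(ca[i], cb[j]) + rec(i + 1, j + 1, "M"))
    }
    if (i <= n) {  # ca[i] against a gap
      g <- if (prev == "A") gapExtend else gapOpen
      best <- max(best, g + rec(i + 1, j, "A"))
    }
    if (j <= m) {  # cb[j] against a gap
      g <- if (prev == "B") gapExtend else gapOpen
      best <- max(best, g + rec(i, j + 1, "B"))
    }
    memo[[key]] <- best
    best
  }
  rec(1, 1, "M")
}

# True exhaustive enumeration of every global alignment (exponential; only
# for very short strings). Returns the maximum score.
alignEnumAll <- function(a, b, scoreFn, gapOpen, gapExtend) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  best <- -Inf
  walk <- function(i, j, prev, acc) {
    if (i > n && j > m) {
      best <<- max(best, acc)
      return(invisible())
    }
    if (i <= n && j <= m)
      walk(i + 1, j + 1, "M", acc + scoreFn(ca[i], cb[j]))
    if (i <= n)
      walk(i + 1, j, "A", acc + if (prev == "A") gapExtend else gapOpen)
    if (j <= m)
      walk(i, j + 1, "B", acc + if (prev == "B") gapExtend else gapOpen)
  }
  walk(1, 1, "M", 0)
  best
}

# Sauvola threshold recomputed pixel by pixel with explicit window loops,
# borders clamped to the image
sauvolaOracle <- function(px, window, k, R) {
  nr <- nrow(px); nc <- ncol(px)
  half <- (window - 1) / 2
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    rs <- max(1, i - half):min(nr, i + half)
    cs <- max(1, j - half):min(nc, j + half)
    w <- px[rs, cs]
    m <- mean(w)
    s <- sqrt(mean((w - m)^2))
    thr <- m * (1 + k * (s / R - 1))
    out[i, j] <- as.numeric(px[i, j] < thr)
  }
  out
}

# Connected-component labeling by BFS in plain R
ccOracle <- function(mask, connectivity) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  if (connectivity == 8) {
    nbr <- expand.grid(dr = -1:1, dc = -1:1)
    nbr <- nbr[!(nbr$dr == 0 & nbr$dc == 0), ]
  } else {
    nbr <- data.frame(dr = c(-1, 0, 0, 1), dc = c(0, -1, 1, 0))
  }
  cur <- 0L
  for (c0 in seq_len(nc)) for (r0 in seq_len(nr)) {
    if (mask[r0, c0] != 0 && lab[r0, c0] == 0L) {
      cur <- cur + 1L
      queue <- list(c(r0, c0))
      lab[r0, c0] <- cur
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (k in seq_len(nrow(nbr))) {
          r <- p[1] + nbr$dr[k]; cc <- p[2] + nbr$dc[k]
          if (r >= 1 && r <= nr && cc >= 1 && cc <= nc &&
              mask[r, cc] != 0 && lab[r, cc] == 0L) {
            lab[r, cc] <- cur
            queue[[length(queue) + 1]] <- c(r, cc)
          }
        }
      }
    }
  }
  lab
}

# despeckle + hole-fill recomputed through the CC oracle
despeckleOracle <- function(mask, minSpeck, minHole) {
  lab <- ccOracle(mask, 8)
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0])
    mask[lab %in% which(areas < minSpeck)] <- 0
  }
  bg <- 1 - mask
  lab <- ccOracle(bg, 4)
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0])
    border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    mask[lab %in% setdiff(which(areas < minHole), border)] <- 1
  }
  mask
}

# random printable text for fuzzing
randomText <- function(len, alphabet = c(LETTERS, letters, 0:9, " ", ".", ",")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

makeStreams <- function(texts) {
  lapply(seq_along(texts), function(i)
    ocrStream(texts[[i]], engineId = paste0("e", i), variantId = "V1_none"))
}
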