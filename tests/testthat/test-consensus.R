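simFn <- local({
  m <- defaultSimilarityMatrix()
  function(a, b) simScore(m, a, b)
})

test_that("levenshtein matches the DP oracle and utils::adist", {
  expect_equal(levenshtein("abc", "abc"), 0L)
  expect_equal(levenshtein("", "abc"), 3L)
  expect_equal(levenshtein("kitten", "sitting"), 3L)
  set.seed(11)
  for (i in 1:60) {
    a <- randomText(sample(0:10, 1)); b <- randomText(sample(0:10, 1))
    expect_identical(levenshtein(a, b), levOracle(a, b))
    expect_identical(levenshtein(a, b), as.integer(adist(a, b)))
  }
})

test_that("the similarity matrix honors the scoring conventions", {
  m <- defaultSimilarityMatrix()
  expect_equal(simScore(m, "a", "a"), 2)   # identical characters
  expect_equal(simScore(m, ".", "W"), -2)  # grossly different shapes
  expect_equal(simScore(m, "l", "1"), 1)   # confusability class
  expect_equal(simScore(m, "A", "a"), 1)   # case pair
  expect_equal(simScore(m, "a", "e"), 0)   # letters, no class
  expect_equal(simScore(m, "a", "7"), -1)  # letter vs digit
  expect_equal(simScore(m, " ", "x"), -2)  # space vs visible
  sm <- scoreMatrix(m, c(letters, LETTERS, 0:9, ".", ",", " "))
  expect_true(all(diag(sm) == 2))
  expect_true(all(sm >= -2 & sm <= 2))
  expect_identical(sm, t(sm))
})

test_that("similarity matrix files round-trip and malformed files error", {
  m <- defaultSimilarityMatrix()
  f <- tempfile(fileext = ".tsv")
  writeSimilarityMatrix(m, f)
  m2 <- readSimilarityMatrix(f)
  alpha <- c("l", "1", "I", "O", "0", "a", "Z", "2")
  expect_identical(scoreMatrix(m, alpha), scoreMatrix(m2, alpha))
  # the shipped default configuration file loads to the default matrix
  shipped <- readSimilarityMatrix(system.file("extdata",
                                              "similarity_default.tsv",
                                              package = "herbocr"))
  expect_identical(scoreMatrix(shipped, alpha), scoreMatrix(m, alpha))
  # out-of-range score
  writeLines(c("l1I\tc1", "O0\tc2", "c1\tc2\t9"), f)
  expect_error(readSimilarityMatrix(f), "range")
  # asymmetric pair
  writeLines(c("l1I\tc1", "O0\tc2", "c1\tc2\t1", "c2\tc1\t-1"), f)
  expect_error(readSimilarityMatrix(f), "symmetr|asymmetric")
  unlink(f)
})

test_that("pairwise alignment scores match the affine-gap conventions", {
  for (s in c("A", "Quercus", "No. 12")) {
    r <- pairwiseAlign(s, s)
    expect_equal(r$score, 2 * nchar(s))
    expect_equal(r$alignedA, s)   # gapless
    expect_equal(r$alignedB, s)
  }
  # one gap run of length 2: open + extend
  expect_equal(pairwiseAlign("AB", "")$score, -3.5)
  expect_equal(pairwiseAlign("", "AB")$score, -3.5)
  expect_equal(pairwiseAlign("", "")$score, 0)
  expect_error(pairwiseAlign(paste0("a", gapChar()), "a"), "sentinel")
})

test_that("alignment equals the optimal-score oracle on random pairs", {
  p <- alignmentParams()
  # the memoized oracle is itself validated against true enumeration
  set.seed(3)
  for (i in 1:20) {
    a <- randomText(sample(0:4, 1), alphabet = c("A", "B", ".", "1"))
    b <- randomText(sample(0:4, 1), alphabet = c("A", "B", ".", "1"))
    expect_equal(alignOracle(a, b, simFn, -3, -0.5),
                 alignEnumAll(a, b, simFn, -3, -0.5))
  }
  set.seed(17)
  for (i in 1:80) {
    a <- randomText(sample(0:8, 1))
    b <- randomText(sample(0:8, 1))
    got <- pairwiseAlign(a, b, p = p)
    expect_equal(got$score, alignOracle(a, b, simFn, -3, -0.5),
                 info = paste(a, "/", b))
    # stripping gaps reproduces the inputs
    expect_equal(gsub(gapChar(), "", got$alignedA, fixed = TRUE), a)
    expect_equal(gsub(gapChar(), "", got$alignedB, fixed = TRUE), b)
  }
})

test_that("outlier pruning drops only far streams and keeps the anchor pair", {
  txts <- c("Flora of Texas", "Flora of Texas", "Flora of Texaz")
  same <- pruneOutliers(makeStreams(txts))
  expect_length(same$streams, 3)
  expect_length(same$prunedIds, 0)
  far <- paste(sample(c(letters, " "), 300, replace = TRUE), collapse = "")
  pr <- pruneOutliers(makeStreams(c(txts, far)), cutoff = 128)
  expect_length(pr$streams, 3)
  expect_length(pr$prunedIds, 1)
  # two streams, arbitrarily far apart: pruning undefined, nothing removed
  two <- pruneOutliers(makeStreams(c("abc", strrep("z", 400))), cutoff = 128)
  expect_length(two$streams, 2)
  # never removes more than n - 2
  set.seed(23)
  for (i in 1:10) {
    n <- sample(3:8, 1)
    txts <- replicate(n, randomText(sample(5:200, 1)))
    out <- pruneOutliers(makeStreams(txts), cutoff = sample(c(5, 50, 128), 1))
    expect_gte(length(out$streams), 2)
  }
})

test_that("pre-alignment substitutions fix spacing and are idempotent", {
  expect_equal(preSubstitutions("Austin , Texas ."), "Austin, Texas.")
  expect_equal(preSubstitutions("already clean."), "already clean.")
  set.seed(2)
  for (i in 1:20) {
    x <- randomText(sample(0:40, 1))
    once <- preSubstitutions(x)
    expect_identical(preSubstitutions(once), once)
  }
})

test_that("progressive MSA aligns small instances exactly", {
  msa <- buildMSA(makeStreams(c("cat", "cat", "cot")))
  expect_equal(msaColumnCount(msa), 3)
  expect_false(any(grepl(gapChar(), msaRows(msa), fixed = TRUE)))
  expect_equal(consensusText(callConsensus(msa)), "cat")
  expect_equal(callConsensus(msa)@support, c(1, 2/3, 1))
  # n identical texts: gapless, column count = text length
  for (n in c(1, 4, 8)) {
    m <- buildMSA(makeStreams(rep("Herbarium 12", n)))
    expect_equal(msaColumnCount(m), 12)
    expect_equal(consensusText(callConsensus(m)), "Herbarium 12")
    expect_equal(callConsensus(m)@support, rep(1, 12))
  }
})

test_that("gap-stripping every MSA row reproduces its input text", {
  set.seed(5)
  for (i in 1:25) {
    n <- sample(2:8, 1)
    base <- randomText(sample(10:60, 1))
    txts <- vapply(seq_len(n), function(k)
      streamText(simulateOCR(base, noiseModel(0.1, 0.05, 0.05,
                                              seed = i * 100 + k))),
      character(1))
    msa <- buildMSA(makeStreams(txts))
    stripped <- gsub(gapChar(), "", msaRows(msa), fixed = TRUE)
    expect_identical(stripped, txts)
    expect_length(unique(nchar(msaRows(msa))), 1)
  }
})

test_that("consensus tie-breaks favor the seed row", {
  msa <- new("MSAResult", rows = c("ab", paste0("a", gapChar())),
             streamIds = c("s1", "s2"), seedIndex = 1L)
  expect_equal(consensusText(callConsensus(msa)), "ab")
  msa2 <- new("MSAResult", rows = c(paste0("a", gapChar()), "ab"),
              streamIds = c("s1", "s2"), seedIndex = 2L)
  expect_equal(consensusText(callConsensus(msa2)), "ab")
})

test_that("consensus recovers the truth better than the average stream", {
  set.seed(77)
  wins <- 0
  for (trial in 1:5) {
    truth <- syntheticLabelText(300, seed = trial)
    streams <- lapply(1:5, function(k)
      simulateOCR(truth, noiseModel(0.06, 0.012, 0.012,
                                    seed = trial * 10 + k)))
    streams <- lapply(streams, function(s) {
      s@text <- preSubstitutions(streamText(s)); s
    })
    cons <- consensusText(callConsensus(buildMSA(streams)))
    cerCons <- levenshtein(cons, truth) / nchar(truth)
    cerStream <- mean(vapply(streams, function(s)
      levenshtein(streamText(s), truth), numeric(1))) / nchar(truth)
    if (cerCons < cerStream) wins <- wins + 1
  }
  expect_gte(wins, 4)
})
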