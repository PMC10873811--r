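test_that("the zero-noise simulator is exact and deterministic", {
  nm <- noiseModel(0, 0, 0)
  expect_equal(streamText(simulateOCR("Flora of Texas", nm)), "Flora of Texas")
  nm2 <- noiseModel(0.2, 0.05, 0.05, seed = 99L)
  a <- simulateOCR("Collected by Smith No. 1234", nm2)
  b <- simulateOCR("Collected by Smith No. 1234", nm2)
  expect_identical(streamText(a), streamText(b))
  expect_identical(a@metadata$events, b@metadata$events)
})

test_that("substitution-only noise preserves length; edits bound Levenshtein", {
  nm <- noiseModel(subRate = 0.3, insRate = 0, delRate = 0, seed = 5L)
  truth <- "Quercus alba near sandy creek bank"
  out <- simulateOCR(truth, nm)
  expect_equal(nchar(streamText(out)), nchar(truth))
  set.seed(31)
  for (i in 1:20) {
    nm3 <- noiseModel(0.1, 0.05, 0.05, seed = sample.int(1e6, 1))
    s <- simulateOCR(truth, nm3)
    expect_lte(levenshtein(truth, streamText(s)), sum(s@metadata$events))
  }
})

test_that("substitution counts match the binomial expectation", {
  truth <- strrep("abcdefghij", 100)  # 1000 chars
  counts <- vapply(1:200, function(seed) {
    s <- simulateOCR(truth, noiseModel(subRate = 0.1, insRate = 0,
                                       delRate = 0, seed = seed))
    s@metadata$events[["sub"]]
  }, numeric(1))
  # n = 1000, p = 0.1: mean 100, per-trial sd sqrt(90), 200 trials
  se <- sqrt(1000 * 0.1 * 0.9 / 200)
  expect_lt(abs(mean(counts) - 100), 3 * se)
})

test_that("substitutions prefer the confusion class", {
  truth <- strrep("O", 400)
  s <- simulateOCR(truth, noiseModel(subRate = 0.5, insRate = 0, delRate = 0,
                                     seed = 4L))
  subs <- setdiff(unique(strsplit(streamText(s), "")[[1]]), "O")
  expect_equal(subs, "0")   # O/0 confusion class
})

test_that("invalid noise rates are rejected", {
  expect_error(noiseModel(subRate = 0.8, delRate = 0.3), "<= 1")
  expect_error(noiseModel(subRate = -0.1), "\\[0, 1\\]")
})

test_that("rendering is deterministic and rejects unprintable characters", {
  a <- renderLabel("Salvia No. 12", labelStyle(speckleDensity = 0.002),
                   seed = 8)
  b <- renderLabel("Salvia No. 12", labelStyle(speckleDensity = 0.002),
                   seed = 8)
  expect_identical(imgPixels(a), imgPixels(b))
  c <- renderLabel("Salvia No. 12", labelStyle(speckleDensity = 0.002),
                   seed = 9)
  expect_false(identical(imgPixels(a), imgPixels(c)))
  expect_error(renderLabel("café"), "unprintable")
})

test_that("rendered speckles appear at the requested density and despeckle removes them", {
  d <- 0.0015
  img <- renderLabel(fixtureText <- "Viola palustris\nnear creek margin",
                     labelStyle(speckleDensity = d), seed = 21)
  A <- imgWidth(img) * imgHeight(img)
  n <- img@metadata$speckleCount
  expect_gt(n, 0.5 * d * A)
  expect_lte(n, round(d * A))
  bin <- sauvolaBinarize(img)
  clean <- despeckleFill(bin, minSpeck = 4, minHole = 4)
  base <- renderLabel(fixtureText, labelStyle(speckleDensity = 0), seed = 21)
  binBase <- despeckleFill(sauvolaBinarize(base), minSpeck = 4, minHole = 4)
  # nearly all specks are gone after despeckling
  expect_lt(sum(imgPixels(clean)) - sum(imgPixels(binBase)), 0.05 * n)
})

test_that("simulated engines transcribe rendered labels through the adapter", {
  img <- renderLabel("Panicum rigidum", labelStyle(), seed = 2,
                     labelId = "L1")
  eng <- simulatedEngine("exact", noiseModel(0, 0, 0))
  s <- runEngine(eng, img)
  expect_equal(streamText(s), "Panicum rigidum")
  expect_equal(s@engineId, "simulated:exact")
  expect_equal(s@variantId, "raw")
  expect_equal(s@labelId, "L1")
  # the stream is reproducible and depends on the variant id
  v1 <- applyVariant(img, "V1")
  noisy <- simulatedEngine("n", noiseModel(0.3, 0.02, 0.02, seed = 1L))
  expect_identical(streamText(runEngine(noisy, v1)),
                   streamText(runEngine(noisy, v1)))
})

test_that("unavailable engines fail loudly instead of returning empty text", {
  tess <- tesseractEngine()
  if (isAvailable(tess)) {
    s <- transcribe(tess, renderLabel("HELLO WORLD 123",
                                      labelStyle(scale = 4), seed = 1))
    expect_gt(nchar(streamText(s)), 0)   # smoke only; content not asserted
  } else {
    expect_error(runEngine(tess, renderLabel("X", labelStyle(), seed = 1)),
                 "tesseract")
  }
  # a simulated image without truth metadata cannot be silently transcribed
  expect_error(transcribe(simulatedEngine(), labelImage(matrix(255, 5, 5))),
               "truthText")
})
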