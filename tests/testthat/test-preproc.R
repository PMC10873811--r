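fixtureText <- "Flora of Texas\nQuercus alba growing\nCollected by Smith No. 1234"

test_that("variant V1 is the identity and unknown variants error", {
  img <- renderLabel(fixtureText, labelStyle(), seed = 3)
  out <- applyVariant(img, "V1")
  expect_identical(imgPixels(out), imgPixels(img))
  expect_equal(out@variantApplied, "V1_none")
  expect_error(applyVariant(img, "V9"), "unknown")
})

test_that("blurScale preserves aspect, mass and the identity case", {
  img <- renderLabel("Some text", labelStyle(), seed = 1)
  # identity: no blur, target equals current long side
  idt <- blurScale(img, blurRadius = 0, targetLongSide = imgWidth(img))
  expect_identical(imgPixels(idt), imgPixels(img))
  # aspect preservation: 100x50 -> target 200 gives 200x100
  m <- matrix(128, 50, 100)
  sc <- blurScale(labelImage(m), blurRadius = 0, targetLongSide = 200)
  expect_equal(c(imgHeight(sc), imgWidth(sc)), c(100, 200))
  # impulse mass conservation under blur (discrete Gaussian sums to 1)
  imp <- matrix(0, 41, 41); imp[21, 21] <- 200
  bl <- blurScale(labelImage(imp), blurRadius = 1.5, targetLongSide = NULL)
  expect_lt(abs(sum(imgPixels(bl)) - 200) / 200, 0.01)
})

test_that("orientation recovers known rotations of a rendered fixture", {
  img <- renderLabel(fixtureText, labelStyle(), seed = 5)
  expect_equal(orientUpright(img)$rotation, 0L)
  rot <- function(deg) labelImage(herbocr:::rotMat(imgPixels(img), deg))
  expect_equal(orientUpright(rot(180))$rotation, 180L)
  expect_equal(orientUpright(rot(90))$rotation, 270L)
  expect_equal(orientUpright(rot(270))$rotation, 90L)
  # blank page: defined fallback with a low-confidence flag
  blank <- orientUpright(labelImage(matrix(255, 40, 60)))
  expect_equal(blank$rotation, 0L)
  expect_true(blank$lowConfidence)
})

test_that("deskew recovers rendered skew within half a degree", {
  for (true in c(3, 0, -2.5)) {
    img <- renderLabel(fixtureText, labelStyle(skew = true), seed = 11)
    d <- deskew(img)
    expect_lt(abs(d$angle - true), 0.5)
    # idempotence: re-estimating on the corrected image gives ~0
    expect_lt(abs(deskew(d$image)$angle), 0.5)
  }
  expect_equal(deskew(labelImage(matrix(255, 30, 30)))$angle, 0)
})

test_that("Sauvola output equals the naive sliding-window recomputation", {
  set.seed(42)
  px <- matrix(runif(32 * 32, 0, 255), 32, 32)
  for (w in c(5, 15)) {
    got <- sauvolaBinarize(labelImage(px), window = w, k = 0.2, R = 128)
    expect_true(all(imgPixels(got) %in% c(0, 1)))
    expect_equal(imgPixels(got), sauvolaOracle(px, w, 0.2, 128))
  }
  # black text on white: oracle equality on a rendered fixture crop
  img <- renderLabel("Ab 12", labelStyle(scale = 2), seed = 2)
  crop <- imgPixels(img)[1:32, 1:32]
  got <- sauvolaBinarize(labelImage(crop), window = 15, k = 0.2, R = 128)
  expect_equal(imgPixels(got), sauvolaOracle(crop, 15, 0.2, 128))
  # constant image: s = 0 so T = m(1 - k) < m, everything is background
  flat <- sauvolaBinarize(labelImage(matrix(128, 20, 20)), window = 5)
  expect_true(all(imgPixels(flat) == 0))
  # oversized window clamps with a warning
  expect_warning(sauvolaBinarize(labelImage(px[1:10, 1:10]), window = 31),
                 "clamp")
})

test_that("despeckle/fill matches the connected-component oracle", {
  bin <- function(m) labelImage(m, binary = TRUE)
  # single isolated foreground pixel is snow
  m <- matrix(0, 10, 10); m[5, 5] <- 1
  expect_equal(sum(imgPixels(despeckleFill(bin(m), minSpeck = 2))), 0)
  # solid block untouched
  solid <- matrix(0, 12, 12); solid[3:10, 3:10] <- 1
  expect_identical(imgPixels(despeckleFill(bin(solid))), solid)
  # interior one-pixel hole is filled
  holed <- solid; holed[6, 6] <- 0
  expect_identical(imgPixels(despeckleFill(bin(holed), minHole = 2)), solid)
  # randomized fixtures against the BFS oracle
  set.seed(9)
  for (i in 1:8) {
    m <- matrix(rbinom(30 * 25, 1, 0.35), 30, 25)
    got <- imgPixels(despeckleFill(bin(m), minSpeck = 4, minHole = 4))
    expect_identical(got, despeckleOracle(m, 4, 4))
    # idempotent
    expect_identical(imgPixels(despeckleFill(labelImage(got, binary = TRUE),
                                             minSpeck = 4, minHole = 4)), got)
  }
  expect_error(despeckleFill(labelImage(matrix(128, 5, 5))), "binary")
})

test_that("the variant chain is cumulative", {
  img <- renderLabel(fixtureText, labelStyle(skew = 1.5), seed = 13)
  pp <- preprocParams(targetLongSide = NULL)
  v2 <- applyVariant(img, "V2", pp)
  v3 <- applyVariant(img, "V3", pp)
  v4 <- applyVariant(img, "V4", pp)
  expect_identical(imgPixels(v3),
                   imgPixels(sauvolaBinarize(v2, pp$sauvolaWindow,
                                             pp$sauvolaK, pp$sauvolaR)))
  expect_identical(imgPixels(v4),
                   imgPixels(despeckleFill(v3, pp$minSpeck, pp$minHole)))
  expect_true(v3@binary && v4@binary)
  # provenance is append-only and records each step
  steps <- vapply(imgProvenance(v4), function(s) s$step, character(1))
  expect_equal(steps[1], "render")
  expect_true(all(c("blur_scale", "orient", "deskew", "sauvola",
                    "despeckle_fill") %in% steps))
})

test_that("images round-trip through PNG with a provenance sidecar", {
  img <- renderLabel("Herbarium 42", labelStyle(), seed = 1)
  f <- tempfile(fileext = ".png")
  writeLabelImage(img, f, sidecar = TRUE)
  back <- readLabelImage(f)
  expect_equal(dim(imgPixels(back)), dim(imgPixels(img)))
  expect_lt(max(abs(imgPixels(back) - imgPixels(img))), 1)
  side <- jsonlite::fromJSON(paste0(f, ".json"), simplifyVector = FALSE)
  expect_equal(side$provenance[[1]]$step, "render")
  unlink(c(f, paste0(f, ".json")))
})
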