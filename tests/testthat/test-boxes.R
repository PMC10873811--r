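test_that("iou matches hand-computed overlap ratios", {
  a <- boundingBox(0, 0, 10, 10)
  expect_equal(iou(a, a), 1)
  expect_equal(iou(a, boundingBox(20, 20, 30, 30)), 0)
  # intersection 5x10 = 50, union 100 + 100 - 50 = 150
  expect_equal(iou(a, boundingBox(5, 0, 15, 10)), 50 / 150)
  # symmetric
  b <- boundingBox(3, 2, 12, 9)
  expect_equal(iou(a, b), iou(b, a))
})

test_that("degenerate boxes are rejected", {
  expect_error(boundingBox(0, 0, 0, 10), "xMin")
  expect_error(boundingBox(5, 5, 10, 5), "yMin")
  expect_error(boundingBox(-1, 0, 5, 5), ">= 0")
})

test_that("iou agrees with a Monte-Carlo point-sampling area oracle", {
  set.seed(101)
  for (rep in 1:15) {
    co <- sort(runif(2, 0, 50)); ro <- sort(runif(2, 0, 50))
    c2 <- sort(runif(2, 0, 50)); r2 <- sort(runif(2, 0, 50))
    a <- boundingBox(co[1], ro[1], co[2] + 1, ro[2] + 1)
    b <- boundingBox(c2[1], r2[1], c2[2] + 1, r2[2] + 1)
    v <- iou(a, b)
    expect_gte(v, 0); expect_lte(v, 1)
    # sample the bounding rectangle of the union
    xr <- range(c(a@xMin, a@xMax, b@xMin, b@xMax))
    yr <- range(c(a@yMin, a@yMax, b@yMin, b@yMax))
    xs <- runif(2e5, xr[1], xr[2]); ys <- runif(2e5, yr[1], yr[2])
    inA <- xs >= a@xMin & xs < a@xMax & ys >= a@yMin & ys < a@yMax
    inB <- xs >= b@xMin & xs < b@xMax & ys >= b@yMin & ys < b@yMax
    mc <- sum(inA & inB) / sum(inA | inB)
    expect_lt(abs(v - mc), 0.01)
  }
})

test_that("reconciliation removes planted outliers and averages corners", {
  ann <- function(x1, y1, x2, y2, type, id)
    labelAnnotation(boundingBox(x1, y1, x2, y2), type, id)
  # unanimity
  u <- reconcileAnnotations(list(ann(0, 0, 10, 10, "typewritten", "a"),
                                 ann(0, 0, 10, 10, "typewritten", "b"),
                                 ann(0, 0, 10, 10, "typewritten", "c")))
  expect_equal(unname(boxCoords(u@box)), c(0, 0, 10, 10))
  expect_equal(u@labelType, "typewritten")
  expect_equal(u@outliersRemoved, 0L)
  expect_true(u@resolved)
  # planted outlier: distant third box, IoU 0 with the others
  r <- reconcileAnnotations(list(ann(0, 0, 10, 10, "typewritten", "a"),
                                 ann(0, 0, 10, 10, "typewritten", "b"),
                                 ann(500, 500, 510, 510, "handwritten", "c")),
                            outlierIoU = 0.5)
  expect_equal(unname(boxCoords(r@box)), c(0, 0, 10, 10))
  expect_equal(r@outliersRemoved, 1L)
  expect_equal(r@nContributing, 2L)
  # corner-wise averaging of non-identical survivors
  r2 <- reconcileAnnotations(list(ann(0, 0, 10, 10, "typewritten", "a"),
                                  ann(2, 0, 12, 10, "typewritten", "b")))
  expect_equal(unname(boxCoords(r2@box)), c(1, 0, 11, 10))
})

test_that("label type is a strict majority vote else unresolved", {
  ann <- function(type, id)
    labelAnnotation(boundingBox(0, 0, 10, 10), type, id)
  r <- reconcileAnnotations(list(ann("typewritten", "a"),
                                 ann("typewritten", "b"),
                                 ann("handwritten", "c")))
  expect_equal(r@labelType, "typewritten")
  expect_true(r@resolved)
  r2 <- reconcileAnnotations(list(ann("typewritten", "a"),
                                  ann("handwritten", "b"),
                                  ann("barcode", "c")))
  expect_equal(r2@labelType, "unresolved")
  expect_false(r2@resolved)
})

test_that("reconciliation is permutation-invariant and rejects bad input", {
  set.seed(7)
  anns <- list(
    labelAnnotation(boundingBox(0, 0, 10, 11), "typewritten", "a"),
    labelAnnotation(boundingBox(1, 0, 11, 10), "typewritten", "b"),
    labelAnnotation(boundingBox(0, 1, 10, 10), "handwritten", "c"),
    labelAnnotation(boundingBox(300, 300, 310, 310), "barcode", "d"))
  ref <- reconcileAnnotations(anns)
  for (i in 1:5) {
    sh <- reconcileAnnotations(sample(anns))
    expect_equal(boxCoords(sh@box), boxCoords(ref@box))
    expect_equal(sh@labelType, ref@labelType)
    expect_equal(sh@outliersRemoved, ref@outliersRemoved)
  }
  expect_error(reconcileAnnotations(list()), "empty")
  expect_error(reconcileAnnotations(list(
    labelAnnotation(boundingBox(0, 0, 10, 10), "typewritten", "a"),
    labelAnnotation(boundingBox(100, 100, 110, 110), "typewritten", "b"))),
    "outlier")
})

test_that("correction clicks are kept only inside labels, smallest box wins", {
  lab <- function(x1, y1, x2, y2)
    reconcileAnnotations(list(labelAnnotation(boundingBox(x1, y1, x2, y2),
                                              "typewritten", "x")))
  labels <- list(lab(0, 0, 10, 10), lab(0, 0, 100, 100))
  kept <- cleanCorrectionClicks(list(correctionClick(5, 5, "correct")),
                                labels)
  expect_length(kept, 1)
  expect_equal(attr(kept[[1]], "labelIndex"), 1L)  # nested: smaller area
  expect_length(cleanCorrectionClicks(list(correctionClick(200, 200,
                                                           "incorrect")),
                                      list(lab(0, 0, 10, 10))), 0)
  # boundary-inclusive
  expect_length(cleanCorrectionClicks(list(correctionClick(10, 10, "correct")),
                                      list(lab(0, 0, 10, 10))), 1)
  # subset of input and idempotent
  clicks <- list(correctionClick(5, 5, "correct"),
                 correctionClick(50, 50, "missed"),
                 correctionClick(500, 500, "incorrect"))
  once <- cleanCorrectionClicks(clicks, labels)
  expect_lte(length(once), length(clicks))
  twice <- cleanCorrectionClicks(once, labels)
  expect_equal(length(twice), length(once))
  expect_length(cleanCorrectionClicks(list(), labels), 0)
})

test_that("prediction scoring matches greedy descending-IoU matching", {
  ann <- function(x1, y1, x2, y2)
    labelAnnotation(boundingBox(x1, y1, x2, y2), "typewritten", "m")
  # identical boxes: perfect score, no phantoms or misses
  s <- scorePredictions(list(ann(0, 0, 10, 10)), list(ann(0, 0, 10, 10)))
  expect_equal(s$meanIoU, 1)
  expect_length(s$phantoms, 0)
  expect_length(s$misses, 0)
  # a prediction with no truth at all is a phantom
  s2 <- scorePredictions(list(ann(0, 0, 10, 10)), list())
  expect_true(is.na(s2$meanIoU))
  expect_equal(nrow(s2$matches), 0)
  expect_equal(s2$phantoms, 1L)
  # two preds, two truths, cross IoUs force the (a,x),(b,y) pairing;
  # expected means computed from hand IoU arithmetic
  a <- ann(0, 0, 10, 10); b <- ann(0, 20, 10, 30)
  x <- ann(0, 0, 10, 9); y <- ann(0, 19, 10, 29)
  expect_equal(iou(a@box, x@box), 0.9)
  expect_equal(iou(b@box, y@box), 90 / 110)
  s3 <- scorePredictions(list(a, b), list(x, y))
  expect_equal(nrow(s3$matches), 2)
  expect_equal(s3$meanIoU, (0.9 + 90 / 110) / 2)
  # adding a phantom never changes matched-pair IoUs
  s4 <- scorePredictions(list(a, b, ann(500, 500, 510, 510)), list(x, y))
  expect_equal(s4$matches$iou, s3$matches$iou)
  expect_equal(s4$phantoms, 3L)
})

test_that("label-record JSON round-trips", {
  lab <- reconcileAnnotations(list(
    labelAnnotation(boundingBox(10, 20, 110, 80), "typewritten", "p1")))
  hand <- reconcileAnnotations(list(
    labelAnnotation(boundingBox(5, 5, 50, 30), "handwritten", "p1")))
  js <- exportLabelsJSON("sheet42", list(lab, hand),
                         texts = list("1" = "Flora of Texas"))
  doc <- readLabelsJSON(js)
  expect_equal(doc$sheet, "sheet42")
  expect_length(doc$labels, 2)
  expect_equal(doc$labels[[1]]$type, "typewritten")
  expect_equal(doc$labels[[1]]$text, "Flora of Texas")
  expect_null(doc$labels[[2]]$text)   # handwritten: not OCR-eligible
  expect_equal(boxCoords(doc$labels[[1]]$box),
               boxCoords(lab@box))
  # write(read(write(x))) == write(x)
  js2 <- exportLabelsJSON(doc$sheet,
                          lapply(doc$labels, function(l)
                            labelAnnotation(l$box, l$type, "import")))
  expect_equal(readLabelsJSON(js2)$labels[[2]]$type, "handwritten")
})
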