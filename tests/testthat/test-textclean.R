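lx <- lexicon(c("Herbarium", "Texas", "Quercus", "alba", "County", "Flora",
                "of", "creek", "sandy"))

test_that("unique-neighbor spell correction fixes OCR glyph errors", {
  r <- postCleanup("Herbar1um of Texas", lex = lx)
  expect_equal(r$text, "Herbarium of Texas")
  expect_equal(r$changes$step, "spell")
  expect_equal(r$changes$before, "Herbar1um")
})

test_that("in-lexicon text is never altered and yields an empty change log", {
  clean <- "Flora of Texas, Quercus alba"
  r <- postCleanup(clean, lex = lx)
  expect_equal(r$text, clean)
  expect_equal(nrow(r$changes), 0)
})

test_that("ambiguous and numeric tokens are left unchanged", {
  amb <- lexicon(c("cat", "cut"))
  r <- postCleanup("cot", lex = amb)   # two distance-1 candidates: abstain
  expect_equal(r$text, "cot")
  # digits are exempt even when a term is one edit away
  numlex <- lexicon(c("12345", "Herbarium"))
  r2 <- postCleanup("12346", lex = numlex)
  expect_equal(r2$text, "12346")
})

test_that("split words are rejoined when only the join is in the lexicon", {
  r <- postCleanup("Herb arium of Texas", lex = lx)
  expect_equal(r$text, "Herbarium of Texas")
  expect_true("join" %in% r$changes$step)
  # fragments that are themselves words stay apart
  r2 <- postCleanup("sandy creek", lex = lx)
  expect_equal(r2$text, "sandy creek")
})

test_that("substitution rules apply in order with word-boundary scopes", {
  rules <- data.frame(pattern = c("[ \t]+([.,;:])", "\\|"),
                      replacement = c("\\1", "l"),
                      scope = c("text", "text"))
  r <- postCleanup("He||o , wor|d .", rules = rules, lex = NULL)
  expect_equal(r$text, "Hello, world.")
})

test_that("postCleanup is idempotent and its change log replays exactly", {
  inputs <- c("Herbar1um of Texas", "Herb arium near sandy creek",
              "Quercus a1ba ; County", "No. 1234 , Texas .")
  for (x in inputs) {
    r <- postCleanup(x, lex = lx)
    again <- postCleanup(r$text, lex = lx)
    expect_equal(again$text, r$text)
    expect_equal(nrow(again$changes), 0)
    expect_equal(replayChanges(x, r$changes), r$text)
  }
})

test_that("lexicon loading merges, deduplicates and is case-aware", {
  f1 <- tempfile(); f2 <- tempfile()
  writeLines(c("Quercus", "alba", "Texas"), f1)
  writeLines(c("Texas", "texas", "Carex"), f2)
  merged <- loadLexicon(c(f1, f2))
  expect_equal(sort(merged@terms),
               sort(c("Quercus", "alba", "Texas", "texas", "Carex")))
  # case-fold fallback finds either casing
  expect_equal(postCleanup("TEXAS", lex = merged)$text, "TEXAS")
  expect_error(loadLexicon(character()), "no lexicon")
  f3 <- tempfile(); writeLines(character(), f3)
  expect_error(loadLexicon(f3), "empty")
  unlink(c(f1, f2, f3))
})
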