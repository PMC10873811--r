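## internal helpers shared across modules

# Evaluate expr with a temporarily seeded RNG, restoring the caller's RNG
# state afterwards. All stochastic fixtures in the package go through this.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Small deterministic string hash onto [0, 2^31): used to derive independent
# sub-seeds for (engine, variant, label) combinations from one master seed.
stableHash <- function(x) {
  h <- 0
  for (cp in utf8ToInt(paste(x, collapse = "\r"))) {
    h <- (h * 31 + cp) %% 2147483647
  }
  as.integer(h)
}

deriveSeed <- function(seed, ...) {
  as.integer((as.numeric(seed) + stableHash(c(...))) %% 2147483647L)
}

chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

`%||%` <- function(a, b) if (is.null(a)) b else a

# md5 of a serialized-to-JSON object, for report provenance
configHash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, force = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}
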