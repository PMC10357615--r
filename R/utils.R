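# Internal helpers shared across modules.

# Deterministic sub-seed for a named stream. All randomness in the package
# flows from one user seed; each table/stage draws from its own substream so
# any single artifact can be regenerated in isolation. Kept below 2^31 - 1.
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  s <- abs(as.numeric(seed)) %% 2147483587
  as.integer((s * 2654435 + h * 97) %% 2147483587)
}

with_substream <- function(seed, stream, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, stream))
  force(code)
}

condition_id <- function(tissue, age, genotype) {
  paste(tissue, age, genotype, sep = ".")
}

assert_seed <- function(seed) {
  if (is.null(seed) || !is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("a single finite numeric `seed` is required (reproducibility contract)")
  }
  invisible(as.integer(seed))
}

# mouse symbols Capitalized-first, human symbols upper-cased; comparisons
# between species must go through the ortholog map, never case-folding.
mouse_case <- function(x) {
  paste0(toupper(substr(x, 1, 1)), tolower(substring(x, 2)))
}

trigamma_inverse <- function(x) {
  # Newton iteration for y with trigamma(y) = x; standard monotone solve.
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-8) break
  }
  y
}
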