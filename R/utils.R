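# Internal helpers: seeding and small numeric utilities.

# Deterministic 31-bit hash of a string (polynomial rolling hash).
hashString <- function(key) {
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  h
}

# Derive an independent RNG substream seed from the master seed and an
# operation key, so that each operation consumes its own stream and adding or
# reordering operations does not perturb the others.
derivedSeed <- function(seed, key) {
  as.integer((as.numeric(seed) %% 65011 * 32749 + hashString(key)) %% 2147483647)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Coerce a PopGrid / GridLayer / matrix / numeric vector to plain values.
asValues <- function(x) {
  if (is(x, "GridLayer")) x@values
  else if (is.matrix(x) || is.numeric(x)) x
  else stop("expected a grid layer, matrix or numeric vector")
}

# Column names of an empty household table.
HH_COLS <- c("id", "x", "y", "stratum", "build_year", "persons")

emptyHouseholds <- function() {
  data.frame(id = integer(), x = numeric(), y = numeric(),
             stratum = factor(character(), levels = STRATA),
             build_year = integer(), persons = integer())
}

checkHouseholds <- function(households) {
  if (!is.data.frame(households) || !all(HH_COLS %in% names(households)))
    stop("household table must have columns ", paste(HH_COLS, collapse = ", "))
  invisible(households)
}
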