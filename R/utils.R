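# Internal helpers: argument checks and deterministic sub-seed derivation.

.checkScalar <- function(x, name, positive = FALSE, min = -Inf, max = Inf) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be strictly positive", name), call. = FALSE)
  if (x < min || x > max)
    stop(sprintf("'%s' must be in [%g, %g]", name, min, max), call. = FALSE)
  invisible(x)
}

.checkProb <- function(x, name) .checkScalar(x, name, min = 0, max = 1)

# Derives a reproducible 31-bit sub-seed from a base seed and a string key,
# so each (subject, task) pair gets its own RNG stream: adding subjects or
# tasks never perturbs the draws of existing ones.
.deriveSeed <- function(seed, key) {
  bytes <- utf8ToInt(paste0(key, ":", format(seed, scientific = FALSE)))
  acc <- 0
  for (b in bytes) acc <- (acc * 131 + b) %% 2147483629
  as.integer(acc + 1)
}

# Evaluates `expr` with a local RNG state seeded from (seed, key); restores
# the caller's RNG afterwards.
.withSeed <- function(seed, key, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(.deriveSeed(seed, key))
  expr
}
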