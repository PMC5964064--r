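#' @include AllGenerics.R
NULL

# Half-away-from-zero rounding; base round() rounds half to even, which would
# make removal counts platform-lore rather than arithmetic. Used for every
# count computation in the package.
roundHalfUp <- function(x) trunc(x + sign(x) * 0.5)

# Draw a child seed from a parent seed without consuming the global RNG
# stream outside the withr scope; keeps all derived seeds < 2^31.
deriveSeed <- function(seed, offset = 0L) {
  as.integer((as.numeric(seed) * 7919 + 104729 * (offset + 1)) %% 2147483647) + 1L
}

# Evaluate expr with a local RNG state seeded by `seed`.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stopfmt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
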