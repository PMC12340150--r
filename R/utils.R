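## Internal helpers shared across modules.

## Fixed labeled offsets deriving one RNG sub-stream per generator stage
## from the master seed.
.STREAM_OFFSETS <- c(proteome = 101L, peptidome = 202L, cohort = 303L,
                     prm = 404L, clinical = 505L, impute = 606L,
                     permute = 707L)

.streamSeed <- function(seed, label) {
  stopifnot(label %in% names(.STREAM_OFFSETS))
  as.integer(seed) + .STREAM_OFFSETS[[label]]
}

## Evaluate expr under a local RNG state; the caller's stream is untouched.
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Lognormal multiplicative noise with mean 1 and the given CV.
.rlnormCV <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

.msg <- function(verbose, ...) if (isTRUE(verbose)) message(sprintf(...))
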