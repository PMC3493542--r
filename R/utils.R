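## internal helpers shared across modules

# round half away from zero; base round() is round-half-even, which would
# shift epoch lengths by one sample for exactly-half sample counts
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# run `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's .Random.seed so simulation helpers do not disturb user RNG
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
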