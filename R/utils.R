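# Internal helpers shared across the package.

# Run `fn` under a local RNG seed without disturbing the caller's stream.
# seed = NULL means "use the ambient RNG state".
.with_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  ge <- globalenv()
  old <- if (exists(".Random.seed", envir = ge, inherits = FALSE)) {
    get(".Random.seed", envir = ge, inherits = FALSE)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = ge, inherits = FALSE)) {
        rm(".Random.seed", envir = ge)
      }
    } else {
      assign(".Random.seed", old, envir = ge)
    }
  })
  set.seed(as.integer(seed))
  fn()
}

.is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min &&
    abs(x - round(x)) < 1e-8
}

.is_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# Serialize doubles so that read-back is bit-exact.
.format_position <- function(x) {
  sprintf("%.17g", x)
}
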