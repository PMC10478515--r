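# Seed handling: every stochastic operation takes an explicit seed and
# restores the caller's RNG state afterwards, so dataset generation and
# training are pure functions of (config, seed).

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
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
  force(code)
}

# Deterministic fan-out of one master seed into per-purpose streams.
# Keeps derived seeds inside the 32-bit integer range.
derive_seed <- function(seed, ..., offset = 0L) {
  parts <- c(as.character(seed), vapply(list(...), as.character, character(1)))
  h <- 0
  for (ch in utf8ToInt(paste(parts, collapse = "/"))) {
    h <- (h * 31 + ch) %% 2147483587
  }
  as.integer((h + offset) %% 2147483587 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_positive <- function(x, what) {
  if (!is.numeric(x) || length(x) == 0L || any(!is.finite(x)) || any(x <= 0)) {
    stop(what, " must be strictly positive and finite", call. = FALSE)
  }
  invisible(x)
}
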