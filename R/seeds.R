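#' Derive a reproducible child seed from a master seed and a stream name
#'
#' All randomness in the package flows from a single master seed through
#' named child streams (e.g. `"split"`, `"rslp-alternative-3"`), so that any
#' sub-result can be re-derived in isolation.  The derivation is a small
#' multiplicative-congruential mix over the stream name, kept strictly below
#' 2^31 so it is always a valid R integer seed.
#'
#' @param master integer master seed.
#' @param stream character scalar naming the random stream.
#' @return an integer in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(master, stream) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stream),
            length(stream) == 1L)
  m <- 2147483647 # 2^31 - 1, Mersenne prime; products stay < 2^53
  s <- (abs(master) %% m)
  s <- (s * 16807 + 12345) %% m
  for (ch in utf8ToInt(stream)) {
    s <- (s * 16807 + ch) %% m
  }
  as.integer(s %% (m - 1L) + 1)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards (local equivalent of withr::with_seed).
with_seed <- function(seed, expr) {
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
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  expr
}
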