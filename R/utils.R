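# internal helpers shared across modules

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All user-facing randomness goes through
# this so that outputs are pure functions of (inputs, seed).
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Round half away from zero (C lround semantics); base round() rounds half to
# even, which would disagree with the projection oracle on *.5 scores.
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# log2(e), used by the bit-score conversion in several modules
LOG2E <- 1 / log(2)

# negative-log sentinel standing in for the HMMER "*" impossible emission;
# large enough that the projected score saturates at the int8 minimum for any
# realistic tau
INF_NLL <- 999.0
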