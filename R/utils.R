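# Internal helpers shared across modules.

# Round-half-up (base round() is round-half-even, which would split 83 into
# 42/41 rather than the intended 43/40 at fraction 43/83... kept explicit).
round_half_up <- function(x) floor(x + 0.5)

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
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

# Derive a named sub-seed from a top-level seed; stays in 32-bit range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% (2^31 - 1))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number.", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name, lower, upper, x))
  }
  invisible(x)
}

# Fixed-width numeric formatting used when serializing report tables so that
# re-rendering a bundle is byte-identical.
format_num <- function(x, digits = 4) {
  ifelse(is.na(x), NA_character_, formatC(x, format = "f", digits = digits))
}
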