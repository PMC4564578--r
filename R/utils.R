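#' @keywords internal
"_PACKAGE"

# Derive a reproducible sub-seed for a named pipeline stage from the master
# seed, so stages can be regenerated independently without sharing a stream.
# Result stays inside the signed 32-bit range required by set.seed().
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes))
  as.integer((abs(as.numeric(seed)) * 48271 + h * 69621) %% 2147483629)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Half-up decimal rounding (round() is round-half-even); percentages in
# reports are conventionally rounded half-up to one decimal.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# p-value formatting convention for text reports: values below the double
# precision floor are printed as an inequality rather than a raw number.
format_pvalue <- function(p) {
  ifelse(p < 2.2e-16, "< 2.2e-16", formatC(p, format = "g", digits = 3))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
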