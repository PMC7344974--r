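# Internal helpers shared across modules.

# Round half away from zero at `digits` decimals.  base::round() rounds half
# to even; band limits are printed at 2 dp with conventional half-up rounding.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # epsilon guards against representation error at exact .xx5 boundaries
  # (e.g. 4.765 * 100 == 476.4999...); safe for magnitudes up to ~1e5
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Canonical form for classification labels: case-folded, unicode dashes and
# the <= sign mapped to ASCII hyphen-forms, whitespace collapsed.  Matching is
# exact after normalisation; no fuzzy matching.
normalize_label <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("[\u2010\u2011\u2012\u2013\u2014]", "-", x)
  x <- gsub("\u2264", "<=", x)
  x <- gsub("\\s+", " ", x)
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_expoband <- function(...) stop(..., call. = FALSE)

# Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so that seeded simulation never perturbs user code.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
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
    set.seed(seed)
  }
  expr
}
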