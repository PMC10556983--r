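# internal helpers shared across modules

#' @importFrom rlang abort warn inform %||%
#' @importFrom withr with_seed
NULL

# run code under a local RNG state; `seed` must be a single finite integerish
with_seed_ <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite number.")
  }
  withr::with_seed(as.integer(seed), code)
}

# derive a stage seed from a run seed; kept below .Machine$integer.max
derive_seed <- function(seed, stage) {
  (as.integer(seed) * 101L + as.integer(stage) * 7919L) %% 2147483587L
}

assert_fraction <- function(x, name, lo = 0, hi = 1,
                            lo_open = FALSE, hi_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (lo_open) x > lo else x >= lo) &&
    (if (hi_open) x < hi else x <= hi)
  if (!ok) {
    abort(sprintf("`%s` must be in %s%s, %s%s.", name,
                  if (lo_open) "(" else "[", format(lo), format(hi),
                  if (hi_open) ")" else "]"))
  }
  invisible(x)
}

`%||%` <- rlang::`%||%`
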