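# Internal helpers shared across modules.

# Deterministic sub-seed derivation: one root seed per study, per-stage /
# per-line seeds derived by a fixed counter scheme. Kept below 2^31 - 1 so the
# result is always a valid set.seed() input.
derive_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  x <- (abs(seed) %% 2147483647) * 7919 + 104729 * (offset %% 262144)
  as.integer(x %% 2147483647)
}

# Run code under a seed without disturbing the caller's RNG state; if seed is
# NULL, use the current RNG stream.
with_seed_or_not <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (x < lower || x > upper) {
    stop(sprintf("`%s` must be in [%s, %s]", name, lower, upper), call. = FALSE)
  }
  invisible(x)
}

assert_columns <- function(df, cols, name = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("`%s` is missing required column(s): %s",
                 name, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

# Morphology channels used throughout: raw and bead-corrected names.
raw_channels <- function() c("fsc", "ssc", "red_b")
corrected_channels <- function() c("fsc_c", "ssc_c", "red_b_c")
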