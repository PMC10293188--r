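# Small internal helpers shared across the package.

# Round half away from zero (presentation rounding for impact tables;
# base::round() rounds half to even).
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Volume-weighted mixing of source fractions: `f` over volume `v`, adding
# `add_v` of composition `add_f`. Returns the fractions of the mixture.
mix_frac <- function(f, v, add_f, add_v) {
  tot <- v + add_v
  if (tot <= 0) return(f)
  (f * v + add_f * add_v) / tot
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  }
  invisible(x)
}
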