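# internal helpers shared across modules

stopf <- function(...) stop(sprintf(...), call. = FALSE)

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# seed = NULL leaves the current stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stopf("`seed` must be a single finite number, got %s", format(seed)[1])
  }
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Uniform mid-rise quantizer emulating an ADC of `bits` resolution over the
# observed signal range; at most 2^bits distinct output levels.
quantize_signal <- function(x, bits) {
  if (is.null(bits) || !is.finite(bits)) return(x)
  rng <- range(x)
  if (diff(rng) == 0) return(x)
  step <- diff(rng) / (2^bits - 1)
  rng[1] + round((x - rng[1]) / step) * step
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

FP_EVENTS <- c("MC", "AO", "AC", "MO")

check_fp_names <- function(x, what) {
  if (!all(FP_EVENTS %in% names(x))) {
    stopf("`%s` must be named with all of %s", what, paste(FP_EVENTS, collapse = ", "))
  }
  x[FP_EVENTS]
}
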