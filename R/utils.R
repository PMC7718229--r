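## internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

rms <- function(x) sqrt(mean(x^2))

## wrap a value into [0, period)
wrap_phase <- function(phase_h, period_h) {
  out <- phase_h %% period_h
  ## guard against exact-period float wrap (e.g. 12 - 1e-17 %% 12)
  out[out >= period_h] <- 0
  out
}

## circular difference b - a modulo period, mapped to (-period/2, period/2]
circular_diff <- function(a, b, period_h) {
  d <- (b - a) %% period_h
  ifelse(d > period_h / 2, d - period_h, d)
}

## deterministic per-stage seed derivation from one master seed; keeps the
## derived stream well below .Machine$integer.max
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629)
}
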