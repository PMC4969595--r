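# Internal helpers shared across modules.

# Classed errors so callers can distinguish failure modes programmatically.
rt_abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "revtraj_error", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Nearest-integer / one-decimal rounding used in reports.
pct <- function(count, total, digits = 0L) {
  if (total == 0) return(NA_real_)
  round(100 * count / total, digits)
}
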