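# shared internal helpers

# classed error so callers/tests can dispatch on failure kind
pc_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "petctlabel_error"), call = call))
}

# round half away from zero toward +Inf, the convention used for all 8-bit
# quantization in the package (floor(x + 0.5), not banker's rounding)
round_half_up <- function(x) floor(x + 0.5)

clip01 <- function(x, lo = 0, hi = 255) pmin(pmax(x, lo), hi)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0

stopifnot_scalar_num <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    pc_stop(sprintf("%s must be a single finite number", what), "validation_error")
}
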