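# Internal helpers shared across modules.

# Classed error so callers/tests can distinguish failure modes.
pl_stop <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "pseudolesion_error", "error", "condition")))
}

stop_invalid <- function(fmt, ...) pl_stop("pl_invalid_parameter", fmt, ...)

# Deterministic round-half-away-from-zero (base round() is half-to-even).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Population (divide-by-n) standard deviation.
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# Fisher z with clipping so identical series stay finite.
fisher_z <- function(r, eps = 1e-7) {
  atanh(pmin(pmax(r, -(1 - eps)), 1 - eps))
}

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == as.integer(x)
}

# Derive a reproducible child seed from a master seed (kept below 2^31).
child_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset) %% 1000L
}
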