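# Internal helpers shared across the package.

`%||%` <- function(x, y) if (is.null(x)) y else x

abort <- function(msg, class = "mgsquant_error", ...) {
  stop(errorCondition(msg, ..., class = c(class, "mgsquant_error")))
}

config_error <- function(msg) abort(msg, class = "mgsquant_config_error")

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x))
    config_error(sprintf("`%s` must be a single integer >= %d (got %s)",
                         name, min, deparse(x)))
  as.integer(x)
}

assert_proportion <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    config_error(sprintf("`%s` must be in [%g, %g] (got %s)", name, lo, hi,
                         deparse(x)))
  as.numeric(x)
}

assert_scalar_num <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min)
    config_error(sprintf("`%s` must be a single number >= %g", name, min))
  as.numeric(x)
}

# Scale tag for abundance matrices ("relative" or "absolute").
mgs_scale <- function(x) attr(x, "mgs_scale")

`mgs_scale<-` <- function(x, value) {
  stopifnot(value %in% c("relative", "absolute"))
  attr(x, "mgs_scale") <- value
  x
}

# Derive a stage-specific seed from a master seed, kept below 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000000L) + as.integer(offset)
}
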