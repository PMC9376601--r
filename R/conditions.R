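# Classed conditions so callers (and the CLI) can distinguish bad files,
# bad data and bad parameters.

stop_format <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("tremorsense_format_error", "tremorsense_error")))
}

stop_data <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("tremorsense_data_error", "tremorsense_error")))
}

stop_param <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("tremorsense_parameter_error", "tremorsense_error")))
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# All stochastic generators in the package route through this, which is what
# makes every simulate_* operation a pure function of its seed arguments.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE
    )
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Derive a child seed from a parent seed and small integer offsets,
# staying inside 32-bit integer range.
derive_seed <- function(seed, ...) {
  off <- c(...)
  s <- as.double(seed)
  for (o in off) s <- (s * 7919 + o * 104729 + 12345) %% 2147483629
  as.integer(s)
}
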