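# Internal helpers shared across modules.

stop_config <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("metaboga_config_error", "error")))
}

stop_format <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("metaboga_format_error", "error")))
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
# Every source of randomness in the package goes through this, so nested
# seeded computations (e.g. CV fold draws inside a GA generation) are
# insulated from each other.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Deterministically spawn `n` child seeds from one master seed; the first k
# children of a master are identical whatever n >= k is, so reduced runs are
# prefixes of full runs.
spawn_seeds <- function(master, n) {
  with_seed(master, sample.int(.Machine$integer.max, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
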