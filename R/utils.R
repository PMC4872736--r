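# Internal utilities shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

spec_error <- function(field, msg) {
  stop(sprintf("invalid spec: field '%s' %s", field, msg), call. = FALSE)
}

check_scalar_num <- function(x, field, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    spec_error(field, "must be a single finite number")
  }
  if (strict && x <= lower) spec_error(field, sprintf("must be > %s", lower))
  if (!strict && x < lower) spec_error(field, sprintf("must be >= %s", lower))
  invisible(x)
}

check_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min) {
    spec_error(field, sprintf("must be an integer >= %d", min))
  }
  as.integer(x)
}

#' Derive a child seed from a master seed and a counter
#'
#' Stage and per-signature seeds are derived from one master seed through a
#' fixed linear-congruential step, so every component of a run is
#' reproducible and independent of iteration order. The result always lies
#' in `[1, 2^31 - 2]`.
#'
#' @param master Master integer seed.
#' @param index Non-negative counter identifying the consumer.
#' @return A single integer seed.
#' @export
child_seed <- function(master, index) {
  stopifnot(is.numeric(master), length(master) == 1L, is.numeric(index),
            length(index) == 1L)
  m <- 2147483647 # 2^31 - 1, prime
  x <- (abs(as.double(master)) %% m) * 48271 + as.double(index) * 7919 + 1
  as.integer(x %% (m - 1) + 1)
}

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's
# global RNG state afterwards. All exported generators use explicit seeds
# and never leak RNG state.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  code
}
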