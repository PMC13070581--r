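# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, restoring the previous
#' RNG state afterwards so surrounding streams are unaffected. A `NULL` seed
#' leaves the current stream untouched.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a per-run seed from a master seed
#'
#' Counter-based derivation so that each (scenario, replicate) pair gets a
#' reproducible seed independent of which other runs are in the batch and of
#' execution order. Kept strictly below 2^31 - 1.
#' @noRd
derive_seed <- function(master_seed, scenario_code, replicate) {
  m <- 2147483647  # 2^31 - 1, prime
  s <- (as.numeric(master_seed) %% m)
  s <- (s * 48271 + (as.numeric(scenario_code) + 1) * 69621) %% m
  s <- (s * 48271 + as.numeric(replicate) * 16807) %% m
  as.integer(s %% (m - 1L)) + 1L
}

stop_if_not_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0))
    stop(sprintf("'%s' must be positive and finite", name), call. = FALSE)
  invisible(x)
}
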