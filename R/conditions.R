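## Classed error conditions used across the package so callers and tests can
## distinguish configuration errors from numerical failures.

fk_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "fk_error"), call = call))
}

fk_config_error <- function(msg) fk_stop(msg, "fk_config_error")
fk_parse_error <- function(msg) fk_stop(msg, "fk_parse_error")
fk_degenerate_match <- function(msg) fk_stop(msg, "fk_degenerate_match")
fk_track_lost <- function(msg) fk_stop(msg, "fk_track_lost")
fk_solver_error <- function(msg) fk_stop(msg, "fk_solver_error")

## Run code with a temporary RNG state seeded from `seed`, restoring the
## caller's state afterwards, so generators are reproducible without
## clobbering the session RNG.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## Cubic ease-in-out ramp on [0, 1]: monotone, zero slope at both ends.
smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}
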