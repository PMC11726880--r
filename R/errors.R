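# Classed error conditions so callers/tests can distinguish failure modes.

cash_abort <- function(message, class) {
  stop(errorCondition(message, class = c(class, "cashr_error", "error")))
}

validation_error <- function(message) cash_abort(message, "cashr_validation_error")
parse_error <- function(message) cash_abort(message, "cashr_parse_error")
io_error <- function(message) cash_abort(message, "cashr_io_error")

# Evaluate `expr` with a temporary RNG seed, restoring the caller's RNG
# state afterwards so seeded internals do not perturb user simulations.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}
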