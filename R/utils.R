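# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the random number generator seeded at `seed`, restoring
#' the caller's RNG state afterwards so generators do not perturb user code.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
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
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Signal a classed error so callers can distinguish failure modes
# (e.g. pb_calibration_failure vs plain input errors).
pb_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "pneumabio_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stopifnot_scalar <- function(x, name, lower = -Inf, upper = Inf,
                             strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    pb_stop(sprintf("'%s' must be a finite numeric scalar", name),
            "pb_input_error")
  }
  ok <- if (strict) (x > lower && x < upper) else (x >= lower && x <= upper)
  if (!ok) {
    pb_stop(sprintf("'%s' = %g outside allowed range (%g, %g)",
                    name, x, lower, upper), "pb_input_error")
  }
  invisible(x)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
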