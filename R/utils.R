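# Internal helpers: classed conditions and seeded evaluation.

stop_with <- function(class, message, ...) {
  cond <- structure(
    class = c(class, "angioquant_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

io_error <- function(message) stop_with("io_error", message)
validation_error <- function(message) stop_with("validation_error", message)
missing_reference_error <- function(message) stop_with("missing_reference_error", message)
degenerate_variance_error <- function(message) stop_with("degenerate_variance_error", message)
packing_error <- function(message, index = NA_integer_)
  stop_with("packing_error", message, index = index)
impossible_state_error <- function(message) stop_with("impossible_state_error", message)

#' Evaluate an expression under a fixed RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded generation never
#' perturbs the global random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0 && x == round(x)

is_scalar_pos <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x > 0
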