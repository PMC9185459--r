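# Internal helpers shared across modules.

# Physical constants (SI units)
.eps0 <- 8.8541878128e-12
.mu0 <- 4e-7 * pi

abort_argument <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("bimqp_argument_error", "bimqp_error")))
}

abort_solver <- function(msg, ..., data = NULL) {
  cond <- errorCondition(sprintf(msg, ...),
                         class = c("bimqp_solver_error", "bimqp_error"))
  cond$data <- data
  stop(cond)
}

abort_training <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("bimqp_training_error", "bimqp_error")))
}

# Hankel functions of the second kind, H_nu^(2)(x) = J_nu(x) - i Y_nu(x),
# matching the e^{j omega t} time convention (outgoing waves).
hankel2 <- function(x, nu = 0) {
  complex(real = besselJ(x, nu), imaginary = -besselY(x, nu))
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
}

is_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Memoization of geometry-dependent operators (Green matrices, penalty
# matrices, receiver Gram matrices). Keys encode the defining geometry.
.op_cache <- new.env(parent = emptyenv())

cache_get <- function(key, expr) {
  if (!is.null(.op_cache[[key]])) return(.op_cache[[key]])
  val <- force(expr)
  .op_cache[[key]] <- val
  val
}

#' Clear the internal operator cache
#'
#' Frees the memoized Green/penalty operators (they are rebuilt on demand).
#' @export
clear_operator_cache <- function() {
  rm(list = ls(.op_cache), envir = .op_cache)
  invisible(NULL)
}
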