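# Internal helpers shared across modules.

#' @keywords internal
ct_stop <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(class, "cervotype_error")))
}

#' @keywords internal
ct_config_error <- function(msg, ...) ct_stop("cervotype_config_error", msg, ...)

#' @keywords internal
ct_format_error <- function(msg, ...) ct_stop("cervotype_format_error", msg, ...)

#' @keywords internal
ct_input_error <- function(msg, ...) ct_stop("cervotype_input_error", msg, ...)

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All stochastic operations in the package funnel through this so that
# results are pure functions of (inputs, seed).
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

#' @keywords internal
stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    ct_config_error(sprintf("`%s` must be a single finite number", name))
  }
  if (positive && x <= 0) {
    ct_config_error(sprintf("`%s` must be > 0", name))
  }
  invisible(x)
}

# Draw one sample from a Dirichlet(alpha) distribution.
#' @keywords internal
rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(x) == 0) { # all shapes tiny: fall back to categorical draw
    x[sample.int(length(alpha), 1L, prob = alpha / sum(alpha))] <- 1
  }
  x / sum(x)
}
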