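# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded internals do not disturb
#' the caller's random-number stream.
#' @noRd
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Positive modulo on the circle: result always in [0, n).
circ_mod <- function(x, n) {
  ((x %% n) + n) %% n
}

stop_validation <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_scalar_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop_validation("`%s` must be a single positive finite number", name)
  }
  invisible(x)
}

check_probability <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop_validation("`%s` must be a probability in [0, 1]", name)
  }
  invisible(x)
}
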