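# Internal helpers shared across modules.

# Response device grid: 0-25 yuan in steps of 0.1.
GRID_STEP <- 0.1

#' Snap values to the response grid
#'
#' Rounds monetary amounts to the 0.1-yuan resolution of the response device
#' used for reciprocity decisions and belief ratings.
#'
#' @param x Numeric vector of amounts (yuan).
#' @param step Grid resolution (yuan). Default 0.1.
#' @return Numeric vector on the grid.
#' @keywords internal
snap_to_grid <- function(x, step = GRID_STEP) {
  round(x / step) * step
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded package functions do not
#' disturb the caller's RNG stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Deterministic child seeds (kept below 2^31) so per-participant simulations
# are reproducible independently of iteration order.
child_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stop_input <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_input(sprintf("`%s` must be a single finite number", name))
  }
  if (x < lo || x > hi) {
    stop_input(sprintf("`%s` = %g is outside [%g, %g]", name, x, lo, hi))
  }
  invisible(x)
}
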