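#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded helpers do not disturb the global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

#' Derive independent sub-seeds from a master seed
#'
#' Each stochastic ingredient of a simulation (response delays, template
#' jitter, sensor noise, drift) draws from its own stream, so changing e.g.
#' the noise level never alters the delays drawn for the same master seed.
#'
#' @param seed master integer seed.
#' @param n number of sub-seeds.
#' @return integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @keywords internal
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Round half away from zero
#'
#' Commercial rounding as used in printed result tables: 0.5 always rounds
#' away from zero (base `round()` rounds half to even).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_out(2.5, 0)   # 3, where round(2.5) gives 2
#' round_half_out(84.766667, 1)
round_half_out <- function(x, digits = 0) {
  p <- 10^digits
  # nudge by a few ulps so values like 0.485 stored as 0.48499999... still
  # round up at the printed precision
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

stop_if_not <- function(cond, ...) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L &&
  is.finite(x) && x >= 1 && x == round(x)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
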