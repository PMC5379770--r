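#' Round half away from zero
#'
#' Fixed-point rounding where .5 always rounds up in magnitude, matching the
#' convention used in the package's printed percentage tables (base R's
#' `round()` rounds half to even).
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Derive a stream seed from a master seed and a label
#'
#' Every stochastic stage of the pipeline draws its own seed from the single
#' configured master seed via this deterministic hash, so stages can be rerun
#' independently while a fixed master seed still fixes the whole run.
#'
#' @param seed master seed (integer)
#' @param label character stage label
#' @return an integer seed in `[0, 2^31 - 1)`
#' @export
fan_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- 0
  for (v in utf8ToInt(label)) h <- (h * 131 + v) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 1000003 + h) %% 2147483647)
}

NUCS <- c("A", "C", "G", "T")

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert_scalar_prob <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop(sprintf("'%s' must be a single number in [%g, %g]", name, lo, hi),
         call. = FALSE)
  invisible(x)
}
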