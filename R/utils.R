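# small shared helpers

# round half away from zero (base round() is banker's rounding)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Derive named substream seeds from a master seed
#'
#' All stochastic generators in the package draw their seed from a single
#' master seed through fixed named substreams (`genome`, `peaks`, `ppa`,
#' `counts`, `models`), so that any stage can be regenerated independently
#' of the others.
#'
#' @param seed master integer seed.
#' @return named integer vector of substream seeds.
#' @export
substream_seeds <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  s <- sample.int(.Machine$integer.max - 1L, 5L)
  names(s) <- c("genome", "peaks", "ppa", "counts", "models")
  s
}

# trapezoidal area under y(x); x need not be sorted
trapezoid_auc <- function(x, y) {
  o <- order(x)
  x <- x[o]; y <- y[o]
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
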