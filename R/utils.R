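# Internal helpers: validation, seed streams, row statistics.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_hepident <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop_hepident(fmt, ...)
  invisible(TRUE)
}

#' Derive a reproducible child seed from a master seed
#'
#' Every stochastic stage of the package draws its randomness from a child
#' seed derived deterministically from one master seed and a stream name, so
#' that stages can be re-run independently yet the whole pipeline stays
#' reproducible from a single integer. The derivation is a fixed polynomial
#' hash of the stream name folded into the master seed, reduced modulo
#' 2^31 - 1 (R integers are 32-bit).
#'
#' @param master integer master seed.
#' @param stream character scalar naming the consumer (e.g. `"counts"`,
#'   `"iteration_17"`).
#' @return An integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @examples
#' child_seed(1L, "counts")
#' @export
child_seed <- function(master, stream) {
  assert_that(is.numeric(master) && length(master) == 1L && is.finite(master),
              "master seed must be a single finite number")
  assert_that(is.character(stream) && length(stream) == 1L,
              "stream must be a single string")
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.double(master) %% m
  for (code in utf8ToInt(stream)) {
    h <- (h * 69069 + code) %% m
  }
  as.integer(h)
}

# Unbiased row-wise variance for a matrix (no matrixStats dependency).
row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2L) return(rep(NA_real_, nrow(x)))
  mu <- rowMeans(x)
  rowSums((x - mu)^2) / (n - 1)
}

# Invert the trigamma function by Newton iteration on 1/psi'(y)
# (monotone, near-linear in that metric); used by the moderated-t
# prior-df moment estimator.
trigamma_inverse <- function(x) {
  assert_that(all(is.finite(x)) && all(x > 0),
              "trigamma_inverse requires finite positive input")
  y <- 0.5 + 1 / x  # starting value, exact as x -> Inf
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-10) break
  }
  y
}
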