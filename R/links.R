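#' Softplus link
#'
#' `softplus(x) = log(1 + exp(x))` maps the real line onto the positive
#' reals and is used throughout the model to keep location parameters
#' (cell-type expression levels, per-spot cell counts) strictly positive.
#' The implementation is stable for large `|x|`: for large positive `x` it
#' returns approximately `x`, for large negative `x` approximately
#' `exp(x)`, with no overflow.
#'
#' @param x Numeric vector (finite).
#' @return Numeric vector of the same length, all entries > 0.
#' @seealso [softplus_inv()], [sigmoid()]
#' @export
#' @examples
#' softplus(0)        # log(2)
#' softplus(50)       # ~50
#' softplus(c(-40, 1))
softplus <- function(x) {
  if (!is.numeric(x)) stop("`x` must be numeric")
  if (anyNA(x) || any(!is.finite(x))) stop("`x` must be finite")
  pmax(x, 0) + log1p(exp(-abs(x)))
}

#' Inverse of the softplus link
#'
#' Returns `x` such that `softplus(x) = y`, i.e. `log(exp(y) - 1)`,
#' computed stably for both small and large `y`.
#'
#' @param y Numeric vector, all entries > 0.
#' @return Numeric vector with `softplus(softplus_inv(y)) == y` up to
#'   floating point.
#' @export
softplus_inv <- function(y) {
  if (!is.numeric(y)) stop("`y` must be numeric")
  if (anyNA(y) || any(!is.finite(y)) || any(y <= 0)) {
    stop("`y` must be finite and > 0")
  }
  y + log1p(-exp(-y))
}

#' Sigmoid link
#'
#' `sigmoid(x) = 1 / (1 + exp(-x))` maps the real line onto (0, 1) and is
#' used to keep the gene-wise negative binomial success probability in its
#' domain. Stable for large `|x|`.
#'
#' @param x Numeric vector (finite).
#' @return Numeric vector with entries strictly in (0, 1).
#' @export
#' @examples
#' sigmoid(0)   # 0.5
#' sigmoid(2) + sigmoid(-2)  # 1
sigmoid <- function(x) {
  if (!is.numeric(x)) stop("`x` must be numeric")
  if (anyNA(x) || any(!is.finite(x))) stop("`x` must be finite")
  out <- numeric(length(x))
  pos <- x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  attributes(out) <- attributes(x)
  out
}

#' Negative binomial log probability mass
#'
#' Log pmf of the negative binomial distribution in the (size, success
#' probability) convention used by the whole model:
#' \deqn{P(X = x) = \frac{\Gamma(x + r)}{\Gamma(r)\, x!} (1-p)^r p^x,}
#' with mean \eqn{r p / (1 - p)}. In this convention sums of independent
#' negative binomials sharing `p` are negative binomial with summed `r`,
#' which is what lets spot-level counts inherit the cell-level model.
#' Note this is the mirror of [stats::dnbinom()]'s `prob` argument:
#' `nb_log_pmf(x, r, p) == dnbinom(x, size = r, prob = 1 - p, log = TRUE)`.
#'
#' @param x Non-negative integer vector of counts.
#' @param r Size parameter(s), > 0.
#' @param p Success probability(-ies), strictly in (0, 1).
#' @return Numeric vector of log probabilities (recycled to common length).
#' @export
#' @examples
#' nb_log_pmf(0, r = 2, p = 0.3)  # 2 * log(0.7)
nb_log_pmf <- function(x, r, p) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x != floor(x))) {
    stop("`x` must contain non-negative integers")
  }
  if (!is.numeric(r) || anyNA(r) || any(r <= 0)) stop("`r` must be > 0")
  if (!is.numeric(p) || anyNA(p) || any(p <= 0) || any(p >= 1)) {
    stop("`p` must be strictly inside (0, 1)")
  }
  lgamma(x + r) - lgamma(r) - lfactorial(x) + r * log1p(-p) + x * log(p)
}
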