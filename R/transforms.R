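#' Convert beta values to M-values
#'
#' The logit2 transform \eqn{M = \log_2(\beta / (1 - \beta))}, the standard
#' variance-stabilising scale for linear modelling of methylation array data.
#' Beta values are clipped to \code{[eps, 1 - eps]} before the transform so
#' that fully (un)methylated probes map to finite M-values.
#'
#' @param beta Numeric vector of beta values in \code{[0, 1]}.
#' @param eps Clipping constant in \code{(0, 0.5)}; default \code{1e-3}.
#' @return Numeric vector of M-values.
#' @seealso [m_to_beta()]
#' @examples
#' beta_to_m(c(0.5, 0.8))  # 0, 2
#' @export
beta_to_m <- function(beta, eps = 1e-3) {
  if (!is.numeric(beta)) stop("`beta` must be numeric")
  if (anyNA(beta)) stop("`beta` contains missing values")
  if (any(beta < 0 | beta > 1)) stop("beta values must lie in [0, 1]")
  if (!is.numeric(eps) || length(eps) != 1L || eps <= 0 || eps >= 0.5)
    stop("`eps` must be a single value in (0, 0.5)")
  b <- pmin(pmax(beta, eps), 1 - eps)
  log2(b / (1 - b))
}

#' Convert M-values back to beta values
#'
#' Inverse of [beta_to_m()] (up to the clipping applied there):
#' \eqn{\beta = 2^M / (2^M + 1)}.
#'
#' @param m Numeric vector of finite M-values.
#' @return Numeric vector of beta values in \code{(0, 1)}.
#' @export
m_to_beta <- function(m) {
  if (!is.numeric(m)) stop("`m` must be numeric")
  if (anyNA(m) || any(!is.finite(m))) stop("`m` must be finite")
  # equivalent to 2^m/(2^m+1) but stable for large |m|
  stats::plogis(m * log(2))
}
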