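#' Power of a 1-dof chi-square test from its noncentrality
#'
#' Upper-tail probability of a noncentral chi-square(1, \code{ncp})
#' variate beyond the central chi-square quantile at \code{1 - alpha}:
#' the power of a 1-dof association test whose statistic has mean shift
#' \code{ncp} under the alternative.
#'
#' @param ncp noncentrality parameter (>= 0); vectorized.
#' @param alpha significance threshold in (0, 1).
#' @return Power value(s) in (0, 1).
#' @examples
#' powerFromNcp(30, 5e-8)
#' @export
powerFromNcp <- function(ncp, alpha) {
  if (any(ncp < 0)) stop("ncp must be nonnegative")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  q <- qchisq(alpha, 1L, lower.tail = FALSE)
  pchisq(q, 1L, ncp = ncp, lower.tail = FALSE)
}

#' Noncentrality achieving a target power
#'
#' Numerical inverse of \code{\link{powerFromNcp}} by monotone
#' root-finding: the unique \code{ncp} whose power at \code{alpha} equals
#' \code{power}.
#'
#' @param power target power, strictly between \code{alpha} and 1.
#' @param alpha significance threshold in (0, 1).
#' @param tol absolute tolerance on the achieved power (default 1e-10).
#' @return The noncentrality parameter.
#' @examples
#' # chi-square inflation to power: 43.7% power at genome-wide alpha,
#' # statistics inflated by 16%
#' ncp <- ncpFromPower(0.437, 5e-8)
#' powerFromNcp(1.16 * ncp, 5e-8)   # ~0.598
#' @export
ncpFromPower <- function(power, alpha, tol = 1e-10) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (power <= alpha || power >= 1)
    stop("power must lie strictly between alpha and 1")
  f <- function(ncp) powerFromNcp(ncp, alpha) - power
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  uniroot(f, c(0, hi), tol = tol / 10)$root
}
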