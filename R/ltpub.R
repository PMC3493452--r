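#' Fit liability-model parameters from published prevalence data (LTPub)
#'
#' Transforms each published prevalence \eqn{K_i} to the liability scale
#' with the standard-normal quantile function, so the model becomes linear:
#' \eqn{\Phi^{-1}(K_i) = c_j (t_i - \bar t_j) + m}. One linear
#' least-squares system with a slope per covariate and a single shared
#' intercept \eqn{m} is then solved in closed form (normal equations).
#' With several covariates, each table is interpreted as the prevalence
#' curve at the means of the other covariates, and the parameters are
#' inferred jointly from the stacked system.
#'
#' By default the fit is unweighted on the liability scale. Setting
#' \code{weighted = TRUE} applies inverse-variance weights from the
#' delta-method variance of the probit transform,
#' \eqn{w_i \propto \phi(\Phi^{-1}(K_i))^2 / (K_i (1 - K_i))}, which
#' down-weights prevalence values near 0 or 1 (useful when the published
#' values carry comparable absolute error on the disease scale).
#'
#' @param tables a \linkS4class{PrevalenceTable}, or a list of them (one
#'   per covariate).
#' @param weighted logical; inverse-variance weighting on the liability
#'   scale (default \code{FALSE}, plain least squares).
#' @return A list with \code{model} (the fitted
#'   \linkS4class{LiabilityModel}) and \code{residuals} (per-observation
#'   liability-scale residuals, in input order).
#' @examples
#' bmi <- PrevalenceTable("BMI", c(18, 21.5, 24.5, 27.5, 30.5, 35),
#'                        c(0.02, 0.03, 0.05, 0.08, 0.13, 0.24),
#'                        referenceMean = 26.5)
#' fitLTPub(bmi)$model   # c = 0.08, m = -1.44 (2 dp)
#' @export
fitLTPub <- function(tables, weighted = FALSE) {
  if (is(tables, "PrevalenceTable")) tables <- list(tables)
  if (!length(tables) || !all(vapply(tables, is, TRUE, "PrevalenceTable")))
    stop("'tables' must be one PrevalenceTable per covariate")
  nms <- vapply(tables, function(x) x@covariateName, "")
  if (anyDuplicated(nms)) stop("duplicate covariate names across tables")
  means <- vapply(tables, function(x)
    if (is.na(x@referenceMean)) mean(x@values) else x@referenceMean, 0)
  nobs <- vapply(tables, function(x) length(x@values), 0L)
  total <- sum(nobs)
  p <- length(tables)
  # design: centered covariate columns (block structure) + intercept
  X <- matrix(0, total, p + 1L)
  y <- numeric(total)
  w <- numeric(total)
  row <- 0L
  for (j in seq_len(p)) {
    idx <- row + seq_len(nobs[j])
    X[idx, j] <- tables[[j]]@values - means[j]
    K <- tables[[j]]@prevalence
    y[idx] <- qnorm(K)
    w[idx] <- dnorm(qnorm(K))^2 / (K * (1 - K))
    row <- row + nobs[j]
  }
  X[, p + 1L] <- 1
  if (!weighted) w[] <- 1
  XtW <- t(X * w)
  xtx <- XtW %*% X
  if (rcond(xtx) < 1e-12)
    stop("singular design: covariate values carry no spread")
  beta <- drop(solve(xtx, XtW %*% y))
  model <- LiabilityModel(coefficients = beta[seq_len(p)],
                          referenceMeans = means, affine = beta[p + 1L],
                          covariateNames = nms)
  list(model = model, residuals = drop(y - X %*% beta))
}

#' Pairwise covariate correlation check
#'
#' The joint LTPub fit treats covariates as independent; this diagnostic
#' reports the squared correlation of every covariate pair in a cohort and
#' flags pairs above a threshold, where the independent-fit approximation
#' starts to degrade.
#'
#' @param cohort an \linkS4class{LTCohort} with at least two covariates.
#' @param threshold flag pairs with \eqn{r^2} above this value
#'   (default 0.05).
#' @return data.frame with columns \code{covariate1}, \code{covariate2},
#'   \code{r2}, \code{flagged}.
#' @export
covariateCorrelationCheck <- function(cohort, threshold = 0.05) {
  X <- cohort@covariates
  if (ncol(X) < 2L) stop("need at least two covariates")
  cc <- complete.cases(X)
  if (sum(cc) < 3L) stop("need at least 3 complete observations")
  X <- X[cc, , drop = FALSE]
  pairs <- utils::combn(colnames(X), 2L)
  r2 <- apply(pairs, 2L, function(p) cor(X[, p[1L]], X[, p[2L]])^2)
  data.frame(covariate1 = pairs[1L, ], covariate2 = pairs[2L, ],
             r2 = r2, flagged = r2 > threshold)
}
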