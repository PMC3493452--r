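# Truncated standard-normal tail means, stable far into the tails.
# Case (upper tail, eps >= tau):   E = phi(tau) / Phibar(tau)
# Control (lower tail, eps < tau): E = -phi(tau) / Phi(tau)
# Computed as exp(log phi - log tail) so neither factor underflows;
# R's pnorm(log.p = TRUE) is accurate to |tau| far beyond 30.
.upperTailMean <- function(tau)
  exp(dnorm(tau, log = TRUE) - pnorm(tau, lower.tail = FALSE, log.p = TRUE))

.lowerTailMean <- function(tau)
  -exp(dnorm(tau, log = TRUE) - pnorm(tau, log.p = TRUE))

#' Impute missing covariates by status-group means
#'
#' Missing covariate values in cases are replaced by the covariate's mean
#' among cases, and likewise for controls.
#'
#' @param cohort an \linkS4class{LTCohort}.
#' @return The cohort with no missing covariate values; observed values
#'   are unchanged.
#' @export
imputeMissingCovariates <- function(cohort) {
  X <- cohort@covariates
  if (!anyNA(X)) return(cohort)
  for (grp in c(0L, 1L)) {
    rows <- cohort@status == grp
    for (j in seq_len(ncol(X))) {
      miss <- rows & is.na(X[, j])
      if (!any(miss)) next
      obs <- X[rows, j]
      obs <- obs[!is.na(obs)]
      if (!length(obs))
        stop("covariate '", colnames(X)[j], "' entirely missing among ",
             if (grp == 1L) "cases" else "controls")
      X[miss, j] <- mean(obs)
    }
  }
  methods::initialize(cohort, covariates = X)
}

#' Posterior mean residual liability per sample
#'
#' Given a fitted liability model and a cohort, computes each sample's
#' residual-liability threshold \eqn{\tau} and the posterior mean
#' \eqn{\hat\epsilon = E(\epsilon \mid z, t)} under the null
#' (\eqn{\epsilon \sim N(0,1)}): the upper-tail truncated-normal mean
#' \eqn{\phi(\tau)/\bar\Phi(\tau)} for cases and the lower-tail mean
#' \eqn{-\phi(\tau)/\Phi(\tau)} for controls. When all of a case's
#' onset-flagged covariates are non-missing, the liability is known to sit
#' exactly at the threshold at onset, so \eqn{\hat\epsilon = \tau} is used
#' instead (exact-onset mode); controls always use the tail expectation.
#'
#' @param model a \linkS4class{LiabilityModel}.
#' @param cohort an \linkS4class{LTCohort}. Covariates are matched to the
#'   model by name. Missing values are imputed internally by status-group
#'   means (\code{\link{imputeMissingCovariates}}); exact-onset mode is
#'   decided from the pre-imputation missingness, so a case with a missing
#'   onset-flagged covariate falls back to the tail expectation.
#' @return A \linkS4class{PosteriorLiability}.
#' @examples
#' m <- LiabilityModel(c(BMI = 0.08), 26.5, -1.44)
#' co <- LTCohort(c("a", "b"), c(1, 0), cbind(BMI = c(24, 35)))
#' posteriorMean(posteriorMeans(m, co))
#' @export
posteriorMeans <- function(model, cohort) {
  p <- length(model@covariateNames)
  observed <- !is.na(cohort@covariates)
  cohort <- imputeMissingCovariates(cohort)
  X <- cohort@covariates
  if (p) {
    if (!all(model@covariateNames %in% colnames(X)))
      stop("cohort lacks model covariate(s): ",
           paste(setdiff(model@covariateNames, colnames(X)), collapse = ", "))
    X <- X[, model@covariateNames, drop = FALSE]
  } else {
    X <- matrix(numeric(0), nrow = length(cohort@sampleIds), ncol = 0)
  }
  tau <- liabilityThreshold(model, X)
  if (!all(is.finite(tau))) stop("non-finite liability threshold")
  case <- cohort@status == 1L
  # a case is in exact-onset mode iff it has at least one onset-flagged
  # model covariate and all such covariates were measured (not imputed)
  onsetCols <- which(colnames(cohort@covariates) %in% model@covariateNames &
                     cohort@onsetFlags)
  onset <- if (length(onsetCols))
    case & rowSums(!observed[, onsetCols, drop = FALSE]) == 0
  else rep(FALSE, length(case))
  eps <- numeric(length(tau))
  eps[case] <- .upperTailMean(tau[case])
  eps[!case] <- .lowerTailMean(tau[!case])
  mode <- ifelse(onset, "onset", "tail")
  eps[onset] <- tau[onset]
  new("PosteriorLiability", sampleIds = cohort@sampleIds, threshold = tau,
      posteriorMean = eps, mode = mode)
}

#' Write / read posterior mean liabilities as delimited text
#'
#' Columns: \code{sample_id}, \code{threshold}, \code{posterior_mean},
#' \code{mode}.
#'
#' @param pm a \linkS4class{PosteriorLiability}.
#' @param path output file.
#' @param sep field delimiter (default tab).
#' @export
writePosteriorLiability <- function(pm, path, sep = "\t") {
  df <- data.frame(sample_id = pm@sampleIds,
                   threshold = formatC(pm@threshold, digits = 15, format = "g"),
                   posterior_mean = formatC(pm@posteriorMean, digits = 15,
                                            format = "g"),
                   mode = pm@mode)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePosteriorLiability
#' @export
readPosteriorLiability <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  new("PosteriorLiability", sampleIds = as.character(df$sample_id),
      threshold = as.numeric(df$threshold),
      posteriorMean = as.numeric(df$posterior_mean), mode = df$mode)
}
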