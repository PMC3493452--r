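#' Residual-liability threshold for given covariate values
#'
#' Under the liability threshold model an individual with covariates
#' \eqn{t} is a case iff the residual liability satisfies
#' \eqn{\epsilon \ge \tau(t)} with
#' \eqn{\tau(t) = -(\sum_j c_j (t_j - \bar t_j) + m)}.
#'
#' Vectorized: \code{t} may be a matrix (samples x covariates), in which
#' case one threshold per row is returned.
#'
#' @param model a \linkS4class{LiabilityModel}.
#' @param t covariate values: a numeric vector with one value per model
#'   covariate, or a matrix with one column per covariate.
#' @return Threshold(s) \eqn{\tau} in liability units.
#' @examples
#' m <- LiabilityModel(c(BMI = 0.08), 26.5, -1.44)
#' liabilityThreshold(m, 24)   # 1.64
#' @export
liabilityThreshold <- function(model, t) {
  p <- length(model@coefficients)
  if (is.matrix(t) || is.data.frame(t)) {
    t <- as.matrix(t)
    if (ncol(t) != p)
      stop("covariate matrix has ", ncol(t), " columns; model expects ", p)
    if (!all(is.finite(t))) stop("covariate values must be finite")
    centered <- sweep(t, 2L, model@referenceMeans)
    return(as.numeric(-(centered %*% model@coefficients + model@affine)))
  }
  if (length(t) != p)
    stop("covariate vector has length ", length(t), "; model expects ", p)
  if (p && !all(is.finite(t))) stop("covariate values must be finite")
  -(sum(model@coefficients * (t - model@referenceMeans)) + model@affine)
}

#' Model-implied disease prevalence at given covariate values
#'
#' The probability that the residual liability exceeds the threshold:
#' \eqn{P(z = 1 \mid t) = \bar\Phi(\tau(t))}, i.e. the standard-normal
#' upper tail beyond \code{\link{liabilityThreshold}}.
#'
#' @inheritParams liabilityThreshold
#' @return Prevalence value(s) strictly in (0, 1).
#' @examples
#' prostate <- LiabilityModel(c(age = 0.05), 50, -2.5)
#' predictPrevalence(prostate, 80)   # ~0.16
#' @export
predictPrevalence <- function(model, t)
  pnorm(liabilityThreshold(model, t), lower.tail = FALSE)

#' Liability-scale variance explained per covariate
#'
#' Fraction of liability variance attributable to covariate \eqn{j}:
#' \eqn{c_j^2 \sigma_j^2 / (1 + \sum_k c_k^2 \sigma_k^2)}, where
#' \eqn{\sigma_j} is the covariate's standard deviation in the study and
#' the 1 is the variance of the residual liability.
#'
#' @param model a \linkS4class{LiabilityModel}.
#' @param covariateSds nonnegative standard deviations, one per covariate.
#' @return Named numeric vector of variance fractions, each in [0, 1).
#' @export
varianceExplained <- function(model, covariateSds) {
  covariateSds <- as.numeric(covariateSds)
  if (length(covariateSds) != length(model@coefficients))
    stop("need one standard deviation per model covariate")
  if (any(!is.finite(covariateSds) | covariateSds < 0))
    stop("standard deviations must be finite and nonnegative")
  v <- model@coefficients^2 * covariateSds^2
  setNames(v / (1 + sum(v)), model@covariateNames)
}

#' Genotype distribution within a (status, covariate) stratum
#'
#' Conditional distribution \eqn{P(g \mid z, t)} of the genotype of a
#' causal SNP with per-allele liability effect \code{gamma} among cases or
#' controls at fixed covariate values, by Bayes' rule over Hardy-Weinberg
#' genotype priors. The genotype enters the liability centered at its
#' population mean \code{2*maf}, so case probability for genotype \eqn{g}
#' is \eqn{\bar\Phi(\tau(t) - \gamma (g - 2\,\mathrm{maf}))}.
#'
#' @param model a \linkS4class{LiabilityModel}.
#' @param t covariate values, one per model covariate.
#' @param status \code{"case"} or \code{"control"}.
#' @param gamma per-allele effect on the liability scale.
#' @param maf population frequency of the counted allele, in (0, 1).
#' @return A list with \code{probabilities} (P(g) for g = 0, 1, 2),
#'   \code{alleleFrequency} (the stratum frequency of the counted allele),
#'   \code{status} and \code{threshold}.
#' @examples
#' t2d <- LiabilityModel(c(BMI = 0.08), 26.5, -1.44)
#' stratumGenotypeDistribution(t2d, 24, "case", gamma = 0.1, maf = 0.5)
#' @export
stratumGenotypeDistribution <- function(model, t, status = c("case", "control"),
                                        gamma, maf) {
  status <- match.arg(status)
  if (!is.finite(maf) || maf <= 0 || maf >= 1)
    stop("maf must lie strictly in (0, 1)")
  tau <- liabilityThreshold(model, t)
  g <- 0:2
  hwe <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
  pcase <- pnorm(tau - gamma * (g - 2 * maf), lower.tail = FALSE)
  w <- hwe * if (status == "case") pcase else 1 - pcase
  if (sum(w) <= 0) stop("degenerate stratum: prevalence 0 or 1")
  p <- w / sum(w)
  list(probabilities = setNames(p, c("0", "1", "2")),
       alleleFrequency = (p[[2]] + 2 * p[[3]]) / 2,
       status = status, threshold = tau)
}

#' Rescale liability-model parameters
#'
#' Multiplies covariate coefficients and/or the affine term by given
#' factors; used to study robustness of the LT statistic to parameter
#' mis-specification.
#'
#' @param model a \linkS4class{LiabilityModel}.
#' @param coefFactors multiplier(s) for the covariate coefficients
#'   (recycled).
#' @param affineFactor multiplier for the affine term.
#' @return The perturbed \linkS4class{LiabilityModel}.
#' @export
perturbModel <- function(model, coefFactors = 1, affineFactor = 1) {
  if (!all(is.finite(c(coefFactors, affineFactor))))
    stop("perturbation factors must be finite")
  LiabilityModel(coefficients = model@coefficients * coefFactors,
                 referenceMeans = model@referenceMeans,
                 affine = model@affine * affineFactor,
                 covariateNames = model@covariateNames)
}

#' Serialize / restore a LiabilityModel as JSON
#'
#' Round-trips exactly: numbers are written at full precision.
#'
#' @param model a \linkS4class{LiabilityModel}.
#' @param path file to write to / read from.
#' @return \code{writeLiabilityModel} invisibly returns \code{path};
#'   \code{readLiabilityModel} returns the model.
#' @export
writeLiabilityModel <- function(model, path) {
  obj <- list(covariate_names = model@covariateNames,
              coefficients = model@coefficients,
              reference_means = model@referenceMeans,
              affine = model@affine)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname writeLiabilityModel
#' @export
readLiabilityModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  LiabilityModel(coefficients = obj$coefficients,
                 referenceMeans = obj$reference_means,
                 affine = obj$affine,
                 covariateNames = as.character(obj$covariate_names))
}
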