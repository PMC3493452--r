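#' @import methods
#' @importFrom stats dnorm pnorm qnorm qchisq pchisq plogis rbinom rnorm
#'   runif lm glm binomial coef complete.cases cor resid setNames var
#'   uniroot ks.test logLik
NULL

#' Liability threshold disease model
#'
#' The model places each individual on an unobserved liability scale
#' \eqn{\phi = \sum_j c_j (t_j - \bar t_j) + m + \epsilon}, where the
#' \eqn{t_j} are clinical covariates (BMI, age, smoking status, ...),
#' \eqn{c_j} are liability-scale covariate coefficients, \eqn{m} is an
#' affine term fixing the disease prevalence at the covariate means, and
#' \eqn{\epsilon} is the residual liability (genetics plus noise), standard
#' normal under the null. An individual is a case iff \eqn{\phi \ge 0}.
#'
#' @slot covariateNames character vector of covariate identifiers (may be
#'   empty for a prevalence-only model).
#' @slot coefficients numeric, liability units per covariate unit.
#' @slot referenceMeans numeric, population means \eqn{\bar t_j} on the
#'   covariate scale.
#' @slot affine length-one numeric, the affine term \eqn{m} (negative for
#'   diseases with prevalence below 50\%).
#' @export
setClass("LiabilityModel",
  representation(covariateNames = "character", coefficients = "numeric",
                 referenceMeans = "numeric", affine = "numeric"))

setValidity("LiabilityModel", function(object) {
  p <- length(object@covariateNames)
  if (length(object@coefficients) != p || length(object@referenceMeans) != p)
    return("coefficients, referenceMeans and covariateNames must have equal length")
  if (length(object@affine) != 1L)
    return("affine must be a single number")
  vals <- c(object@coefficients, object@referenceMeans, object@affine)
  if (!all(is.finite(vals)))
    return("all model parameters must be finite")
  prev <- pnorm(object@affine)   # upper tail beyond -m
  if (prev <= 0 || prev >= 1)
    return("prevalence at the covariate means must lie strictly in (0, 1)")
  TRUE
})

#' Construct a LiabilityModel
#'
#' @param coefficients numeric vector of liability-scale covariate
#'   coefficients \eqn{c_j} (possibly length zero).
#' @param referenceMeans numeric vector of covariate reference means
#'   \eqn{\bar t_j}.
#' @param affine the affine term \eqn{m}.
#' @param covariateNames optional covariate names; defaults to the names of
#'   \code{coefficients} or \code{"t1"}, \code{"t2"}, ...
#' @return A \linkS4class{LiabilityModel}.
#' @examples
#' # toy type 2 diabetes model: prevalence rises with BMI
#' m <- LiabilityModel(coefficients = c(BMI = 0.08),
#'                     referenceMeans = 26.5, affine = -1.44)
#' predictPrevalence(m, 26.5)   # prevalence at the mean BMI
#' @export
LiabilityModel <- function(coefficients = numeric(0), referenceMeans = numeric(0),
                           affine, covariateNames = NULL) {
  cc <- as.numeric(coefficients)
  if (is.null(covariateNames)) {
    covariateNames <- names(coefficients)
    if (is.null(covariateNames))
      covariateNames <- if (length(cc)) paste0("t", seq_along(cc)) else character(0)
  }
  new("LiabilityModel", covariateNames = as.character(covariateNames),
      coefficients = unname(cc), referenceMeans = unname(as.numeric(referenceMeans)),
      affine = as.numeric(affine))
}

setMethod("show", "LiabilityModel", function(object) {
  cat("LiabilityModel\n")
  if (length(object@covariateNames)) {
    terms <- sprintf("%+.4g*(%s-%.4g)", object@coefficients,
                     object@covariateNames, object@referenceMeans)
    cat("  phi =", paste(terms, collapse = " "),
        sprintf("%+.4g + eps\n", object@affine))
  } else {
    cat(sprintf("  phi = %+.4g + eps   (prevalence-only model)\n", object@affine))
  }
  cat(sprintf("  prevalence at covariate means: %.4g\n", pnorm(object@affine)))
})

#' @describeIn LiabilityModel-class covariate coefficients \eqn{c_j}.
#' @param object,x a \code{LiabilityModel}.
#' @param ... ignored.
#' @export
setMethod("coef", "LiabilityModel", function(object, ...)
  setNames(object@coefficients, object@covariateNames))

#' Accessors for LiabilityModel
#'
#' @param x a \linkS4class{LiabilityModel}.
#' @return \code{referenceMeans} returns the named covariate reference
#'   means; \code{affineTerm} the affine term; \code{covariateNames} the
#'   covariate identifiers.
#' @export
referenceMeans <- function(x) setNames(x@referenceMeans, x@covariateNames)

#' @rdname referenceMeans
#' @export
affineTerm <- function(x) x@affine

#' @rdname referenceMeans
#' @export
covariateNames <- function(x) x@covariateNames

#' Published prevalence observations for one covariate
#'
#' Holds published disease prevalence values observed over a range of one
#' clinical covariate, the raw material for \code{\link{fitLTPub}}. When a
#' model has several covariates, each table is read as the prevalence curve
#' at the means of the other covariates.
#'
#' @slot covariateName identifier of the covariate.
#' @slot values covariate values \eqn{t_i}.
#' @slot prevalence published prevalence \eqn{K_i}, strictly in (0, 1).
#' @slot referenceMean reference mean \eqn{\bar t}; \code{NA} means "use
#'   the mean of \code{values}".
#' @export
setClass("PrevalenceTable",
  representation(covariateName = "character", values = "numeric",
                 prevalence = "numeric", referenceMean = "numeric"))

setValidity("PrevalenceTable", function(object) {
  if (length(object@covariateName) != 1L) return("covariateName must be length 1")
  if (length(object@values) != length(object@prevalence))
    return("values and prevalence must have equal length")
  if (!all(is.finite(object@values))) return("covariate values must be finite")
  if (any(object@prevalence <= 0 | object@prevalence >= 1))
    return("every prevalence must lie strictly in (0, 1)")
  if (length(unique(object@values)) < 2L)
    return("need at least 2 distinct covariate values")
  if (length(object@referenceMean) != 1L) return("referenceMean must be length 1")
  TRUE
})

#' Construct a PrevalenceTable
#'
#' @param covariateName covariate identifier, e.g. \code{"BMI"}.
#' @param values covariate values at which prevalence was published.
#' @param prevalence prevalence at each value, as proportions in (0, 1).
#' @param referenceMean optional reference mean \eqn{\bar t}; defaults to
#'   the mean of \code{values}.
#' @return A \linkS4class{PrevalenceTable}.
#' @examples
#' PrevalenceTable("age", c(60, 70, 80), c(0.02, 0.08, 0.14),
#'                 referenceMean = 50)
#' @export
PrevalenceTable <- function(covariateName, values, prevalence,
                            referenceMean = NA_real_) {
  new("PrevalenceTable", covariateName = as.character(covariateName),
      values = as.numeric(values), prevalence = as.numeric(prevalence),
      referenceMean = as.numeric(referenceMean))
}

setMethod("show", "PrevalenceTable", function(object) {
  cat(sprintf("PrevalenceTable for '%s' (%d observations)\n",
              object@covariateName, length(object@values)))
  print(data.frame(value = object@values, prevalence = object@prevalence))
  rm <- if (is.na(object@referenceMean)) mean(object@values) else object@referenceMean
  cat(sprintf("  reference mean: %.4g%s\n", rm,
              if (is.na(object@referenceMean)) " (from data)" else ""))
})

#' Case-control cohort with clinical covariates
#'
#' @slot sampleIds sample identifiers.
#' @slot status integer, 0 = control, 1 = case.
#' @slot covariates numeric matrix, samples x covariates; \code{NA} allowed
#'   (see \code{\link{imputeMissingCovariates}}).
#' @slot onsetFlags logical per covariate: \code{TRUE} if case values were
#'   measured at disease onset, enabling the exact-threshold posterior mode.
#' @export
setClass("LTCohort",
  representation(sampleIds = "character", status = "integer",
                 covariates = "matrix", onsetFlags = "logical"))

setValidity("LTCohort", function(object) {
  n <- length(object@sampleIds)
  if (n < 1L) return("cohort must contain at least one sample")
  if (anyDuplicated(object@sampleIds)) return("duplicate sample ids")
  if (length(object@status) != n) return("status length must match samples")
  if (!all(object@status %in% c(0L, 1L))) return("status must be 0/1")
  if (nrow(object@covariates) != n)
    return("covariate matrix rows must match samples")
  if (ncol(object@covariates) != length(object@onsetFlags))
    return("onsetFlags must have one entry per covariate")
  if (is.null(colnames(object@covariates)) && ncol(object@covariates) > 0)
    return("covariate matrix must have column names")
  TRUE
})

#' Construct an LTCohort
#'
#' @param sampleIds character sample identifiers.
#' @param status 0/1 case-control status per sample.
#' @param covariates numeric matrix or data.frame of covariate values
#'   (samples x covariates), \code{NA} for missing; may have zero columns.
#' @param onsetFlags logical, one per covariate: case values measured at
#'   disease onset. Default all \code{FALSE}.
#' @return An \linkS4class{LTCohort}.
#' @export
LTCohort <- function(sampleIds, status, covariates = NULL, onsetFlags = NULL) {
  n <- length(sampleIds)
  if (is.null(covariates))
    covariates <- matrix(numeric(0), nrow = n, ncol = 0)
  covariates <- as.matrix(covariates)
  storage.mode(covariates) <- "double"
  if (is.null(onsetFlags)) onsetFlags <- rep(FALSE, ncol(covariates))
  new("LTCohort", sampleIds = as.character(sampleIds),
      status = as.integer(status), covariates = covariates,
      onsetFlags = as.logical(onsetFlags))
}

setMethod("show", "LTCohort", function(object) {
  cat(sprintf("LTCohort: %d samples (%d cases, %d controls), %d covariate(s)",
              length(object@sampleIds), sum(object@status == 1L),
              sum(object@status == 0L), ncol(object@covariates)))
  if (ncol(object@covariates))
    cat(":", paste0(colnames(object@covariates),
                    ifelse(object@onsetFlags, " [at onset]", ""),
                    collapse = ", "))
  nmiss <- sum(is.na(object@covariates))
  cat("\n")
  if (nmiss) cat(sprintf("  %d missing covariate value(s)\n", nmiss))
})

#' Accessors for LTCohort
#' @param x an \linkS4class{LTCohort}.
#' @export
sampleIds <- function(x) x@sampleIds

#' @rdname sampleIds
#' @export
caseStatus <- function(x) x@status

#' @rdname sampleIds
#' @export
covariateValues <- function(x) x@covariates

#' @rdname sampleIds
#' @export
onsetFlags <- function(x) setNames(x@onsetFlags, colnames(x@covariates))

#' Per-sample posterior mean residual liability
#'
#' Result of \code{\link{posteriorMeans}}: for each sample the liability
#' threshold \eqn{\tau} implied by its covariates and the posterior mean
#' \eqn{\hat\epsilon = E(\epsilon \mid z, t)} used as the quantitative
#' pseudo-phenotype in the LT association test.
#'
#' @slot sampleIds sample identifiers.
#' @slot threshold per-sample residual-liability threshold \eqn{\tau}.
#' @slot posteriorMean per-sample \eqn{\hat\epsilon}.
#' @slot mode \code{"tail"} (truncated-normal expectation) or
#'   \code{"onset"} (exact threshold, covariates measured at onset).
#' @export
setClass("PosteriorLiability",
  representation(sampleIds = "character", threshold = "numeric",
                 posteriorMean = "numeric", mode = "character"))

setValidity("PosteriorLiability", function(object) {
  n <- length(object@sampleIds)
  if (length(object@threshold) != n || length(object@posteriorMean) != n ||
      length(object@mode) != n)
    return("all slots must have one entry per sample")
  if (!all(object@mode %in% c("tail", "onset")))
    return("mode must be 'tail' or 'onset'")
  if (!all(is.finite(object@threshold)) || !all(is.finite(object@posteriorMean)))
    return("thresholds and posterior means must be finite")
  TRUE
})

setMethod("show", "PosteriorLiability", function(object) {
  cat(sprintf("PosteriorLiability: %d samples (%d exact-onset)\n",
              length(object@sampleIds), sum(object@mode == "onset")))
  cat(sprintf("  posterior mean range: [%.4g, %.4g]\n",
              min(object@posteriorMean), max(object@posteriorMean)))
})

#' Accessors for PosteriorLiability
#' @param x a \linkS4class{PosteriorLiability}.
#' @export
posteriorMean <- function(x) setNames(x@posteriorMean, x@sampleIds)

#' @rdname posteriorMean
#' @export
liabilityThresholds <- function(x) setNames(x@threshold, x@sampleIds)

#' @rdname posteriorMean
#' @export
posteriorMode <- function(x) setNames(x@mode, x@sampleIds)

#' SNP dosage matrix
#'
#' Thin wrapper around \link[SummarizedExperiment]{SummarizedExperiment}
#' with one assay \code{"dosage"}: SNPs as rows, samples as columns, ALT
#' allele dosages in [0, 2] (or \code{NA}). Row metadata carries
#' \code{snp_id}, \code{chr}, \code{pos}, \code{ref}, \code{alt}.
#'
#' @export
#' @import SummarizedExperiment
setClass("GenotypeMatrix", contains = "SummarizedExperiment")

setValidity("GenotypeMatrix", function(object) {
  if (!("dosage" %in% SummarizedExperiment::assayNames(object)))
    return("GenotypeMatrix must carry a 'dosage' assay")
  d <- SummarizedExperiment::assay(object, "dosage")
  if (any(d < 0 | d > 2, na.rm = TRUE))
    return("dosages must lie in [0, 2] or be NA")
  if (is.null(colnames(object))) return("sample (column) names are required")
  TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param dosages numeric matrix of ALT-allele dosages, samples x SNPs
#'   (transposed internally to the SNPs x samples assay layout), values in
#'   [0, 2] or \code{NA}.
#' @param snpInfo optional data.frame with columns \code{snp_id},
#'   \code{chr}, \code{pos}, \code{ref}, \code{alt} (one row per SNP).
#' @return A \linkS4class{GenotypeMatrix}.
#' @export
GenotypeMatrix <- function(dosages, snpInfo = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  d <- t(dosages)                       # SNPs x samples
  if (is.null(rownames(d))) rownames(d) <- paste0("snp", seq_len(nrow(d)))
  if (is.null(snpInfo))
    snpInfo <- data.frame(snp_id = rownames(d), chr = NA_character_,
                          pos = NA_integer_, ref = NA_character_,
                          alt = NA_character_)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = d), rowData = snpInfo)
  rownames(se) <- snpInfo$snp_id
  new("GenotypeMatrix", se)
}

#' Accessors for GenotypeMatrix
#'
#' @param x a \linkS4class{GenotypeMatrix}.
#' @return \code{dosages} returns the samples x SNPs dosage matrix;
#'   \code{snpInfo} the per-SNP metadata data.frame.
#' @export
dosages <- function(x) t(SummarizedExperiment::assay(x, "dosage"))

#' @rdname dosages
#' @export
snpInfo <- function(x) as.data.frame(SummarizedExperiment::rowData(x))

setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf("GenotypeMatrix: %d SNP(s) x %d sample(s)\n",
              nrow(object), ncol(object)))
  d <- SummarizedExperiment::assay(object, "dosage")
  cat(sprintf("  missing dosages: %d\n", sum(is.na(d))))
})
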