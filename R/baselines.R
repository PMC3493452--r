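# Comparison statistics: logistic-regression-family tests of case-control
# status on genotype. All fits use stats::glm (IRLS); the headline
# statistic is the likelihood-ratio chi-square for the genotype term(s).

.flagFit <- function(fit, maxAbsCoef = 50) {
  co <- coef(fit)
  # a residual deviance of ~0 with residual df left signals complete
  # separation even when IRLS reports convergence
  separated <- fit$deviance < 1e-7 && fit$df.residual > 0
  fit$converged && all(is.finite(co)) && max(abs(co)) <= maxAbsCoef &&
    !separated
}

.glmCtrl <- stats::glm.control(epsilon = 1e-8, maxit = 100)

#' Logistic-regression association test
#'
#' Maximum-likelihood logistic regression of case-control status on
#' genotype dosage, optionally with covariates, reporting the
#' likelihood-ratio chi-square (1 dof) for the genotype term (Wald
#' available via \code{type}). With sampling \code{weights} the fit is
#' inverse-probability-weighted and the Wald statistic uses a robust
#' (sandwich) variance.
#'
#' @param status 0/1 case-control status.
#' @param genotype dosage in [0, 2].
#' @param covariates optional numeric matrix of adjustment covariates.
#' @param weights optional inverse-probability sampling weights (the
#'   caller supplies true inverse sampling fractions).
#' @param type \code{"lrt"} (default) or \code{"wald"}.
#' @return list with \code{statistic}, \code{p}, \code{logOr} (per-allele
#'   log odds ratio), \code{se}, \code{converged}. Non-convergence or
#'   separation (|coefficient| > 50) flags the fit and yields \code{NA}
#'   statistics rather than a misleading p-value.
#' @export
logrTest <- function(status, genotype, covariates = NULL, weights = NULL,
                     type = c("lrt", "wald")) {
  type <- match.arg(type)
  status <- as.numeric(status)
  if (length(unique(status)) < 2L)
    stop("status must contain both cases and controls")
  dat <- data.frame(z = status, g = as.numeric(genotype))
  Xc <- if (is.null(covariates)) NULL else as.matrix(covariates)
  fml1 <- if (is.null(Xc)) z ~ g else z ~ g + Xc
  fml0 <- if (is.null(Xc)) z ~ 1 else z ~ Xc
  if (is.null(weights)) {
    fit1 <- glm(fml1, family = binomial(), data = dat, control = .glmCtrl)
    fit0 <- glm(fml0, family = binomial(), data = dat, control = .glmCtrl)
    if (!.flagFit(fit1))
      return(list(statistic = NA_real_, p = NA_real_, logOr = NA_real_,
                  se = NA_real_, converged = FALSE))
    b <- coef(fit1)[["g"]]
    se <- sqrt(diag(stats::vcov(fit1))[["g"]])
    stat <- if (type == "lrt") fit0$deviance - fit1$deviance else (b / se)^2
  } else {
    dat$w <- as.numeric(weights)
    fit1 <- suppressWarnings(glm(fml1, family = stats::quasibinomial(),
                                 data = dat, weights = w, control = .glmCtrl))
    if (!.flagFit(fit1))
      return(list(statistic = NA_real_, p = NA_real_, logOr = NA_real_,
                  se = NA_real_, converged = FALSE))
    b <- coef(fit1)[["g"]]
    se <- sqrt(diag(sandwich::sandwich(fit1))[["g"]])
    stat <- (b / se)^2   # robust Wald; LRT is invalid under IPW
  }
  list(statistic = stat, p = pchisq(stat, 1L, lower.tail = FALSE),
       logOr = b, se = se, converged = TRUE)
}

#' Joint test of genetic main effect and gene x covariate interaction
#'
#' 2-dof likelihood-ratio test of \{genotype, genotype x covariate\}
#' jointly, with the covariate main effect present in both the null and
#' the alternative model. Also reports the equivalent 1-dof chi-square
#' (same upper-tail probability) for comparison with 1-dof tests.
#'
#' @inheritParams logrTest
#' @param covariate the interacting clinical covariate.
#' @return list with \code{statistic} (2 dof), \code{p},
#'   \code{statistic1dof}, \code{converged}.
#' @export
gGxeTest <- function(status, genotype, covariate) {
  dat <- data.frame(z = as.numeric(status), g = as.numeric(genotype),
                    x = as.numeric(covariate))
  if (length(unique(dat$z)) < 2L)
    stop("status must contain both cases and controls")
  fit1 <- glm(z ~ g * x, family = binomial(), data = dat, control = .glmCtrl)
  fit0 <- glm(z ~ x, family = binomial(), data = dat, control = .glmCtrl)
  if (!.flagFit(fit1))
    return(list(statistic = NA_real_, p = NA_real_,
                statistic1dof = NA_real_, converged = FALSE))
  stat <- fit0$deviance - fit1$deviance
  list(statistic = stat, p = pchisq(stat, 2L, lower.tail = FALSE),
       statistic1dof = chisqDfConvert(stat, 2L, 1L), converged = TRUE)
}

#' 1-dof gene x covariate interaction test
#'
#' Likelihood-ratio test of the interaction term given the genetic and
#' covariate main effects: the 2-dof joint statistic
#' (\code{\link{gGxeTest}}) minus the 1-dof covariate-adjusted genotype
#' likelihood-ratio statistic, by the nesting of the three models.
#'
#' @inheritParams gGxeTest
#' @return list with \code{statistic} (1 dof), \code{p}, \code{converged}.
#' @export
gxe1dofTest <- function(status, genotype, covariate) {
  dat <- data.frame(z = as.numeric(status), g = as.numeric(genotype),
                    x = as.numeric(covariate))
  fit1 <- glm(z ~ g * x, family = binomial(), data = dat, control = .glmCtrl)
  fit0 <- glm(z ~ g + x, family = binomial(), data = dat, control = .glmCtrl)
  if (!.flagFit(fit1))
    return(list(statistic = NA_real_, p = NA_real_, converged = FALSE))
  stat <- fit0$deviance - fit1$deviance
  list(statistic = stat, p = pchisq(stat, 1L, lower.tail = FALSE),
       converged = TRUE)
}

#' Subset logistic regression (e.g. low-BMI cases versus all controls)
#'
#' Logistic regression of status on genotype retaining every control and
#' only the cases on the stated side of a covariate cutoff, the
#' "early-onset / low-covariate cases" design.
#'
#' @inheritParams gGxeTest
#' @param cutoff covariate cutoff splitting the cases.
#' @param direction keep cases with covariate \code{"below"} (<=) or
#'   \code{"above"} (>) the cutoff.
#' @return As \code{\link{logrTest}}, plus \code{nCasesKept}.
#' @export
logrSubsetTest <- function(status, genotype, covariate, cutoff,
                           direction = c("below", "above")) {
  direction <- match.arg(direction)
  status <- as.numeric(status)
  covariate <- as.numeric(covariate)
  keepCase <- if (direction == "below") covariate <= cutoff else covariate > cutoff
  keep <- status == 0 | keepCase
  if (!any(status == 1 & keepCase)) stop("cutoff retains no cases")
  res <- logrTest(status[keep], genotype[keep])
  res$nCasesKept <- sum(status == 1 & keepCase)
  res
}

#' Case-only gene x covariate test
#'
#' Logistic regression, among cases only, of covariate group membership on
#' genotype: a classical case-only interaction test.
#'
#' @param covariateGroup binary group indicator among cases (0/1, logical,
#'   or a two-level factor), e.g. low versus high BMI.
#' @param genotype dosage in [0, 2] for the same cases.
#' @return As \code{\link{logrTest}}.
#' @export
caseOnlyTest <- function(covariateGroup, genotype) {
  if (is.factor(covariateGroup) || is.character(covariateGroup)) {
    f <- factor(covariateGroup)
    if (nlevels(f) != 2L) stop("covariateGroup must have exactly two levels")
    covariateGroup <- as.integer(f) - 1L
  }
  if (length(unique(covariateGroup)) < 2L)
    stop("both covariate groups must be present")
  logrTest(covariateGroup, genotype)
}
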