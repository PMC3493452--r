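#' LT association test: trend test of posterior mean liability on genotype
#'
#' The informed-conditioning association statistic: a generalized Armitage
#' trend test of the posterior mean residual liability \eqn{\hat\epsilon}
#' against ALT-allele dosage, \eqn{\chi^2 = N r^2(g, \hat\epsilon)} with 1
#' degree of freedom. With \eqn{K} nuisance covariates (e.g. principal
#' components) both genotype and \eqn{\hat\epsilon} are residualized on
#' them (intercept included) and the statistic is \eqn{(N - K - 1) r^2} of
#' the residuals, generalizing EIGENSTRAT. The statistic is a score test:
#' it equals \eqn{U^2/\widehat{Var}(U)} with
#' \eqn{U = \sum_i g_i \hat\epsilon_i} on centered quantities.
#'
#' Samples are matched between \code{pm} and \code{geno} by sample id.
#' Missing genotypes are handled per SNP by complete-case analysis
#' (\eqn{N} adjusts per SNP) or, with \code{imputeDosage = TRUE}, by
#' mean-dosage imputation. Monomorphic SNPs and zero-variance
#' \eqn{\hat\epsilon} yield \code{NA} statistics flagged in the
#' \code{defined} column rather than 0.
#'
#' @param pm a \linkS4class{PosteriorLiability}.
#' @param geno a \linkS4class{GenotypeMatrix}.
#' @param nuisance optional numeric matrix of nuisance covariates (rows
#'   matched to \code{pm} sample order or named by sample id).
#' @param imputeDosage replace missing dosages by the SNP mean instead of
#'   dropping samples (default \code{FALSE}).
#' @param model optional \linkS4class{LiabilityModel}; when supplied, the
#'   liability-scale effect of each SNP is also converted to a per-allele
#'   odds ratio at the covariate means via
#'   \code{\link{liabilityEffectToOR}}.
#' @return data.frame with one row per SNP: \code{snp_id}, \code{chr},
#'   \code{pos}, \code{n}, \code{af}, \code{statistic} (1-dof chi-square),
#'   \code{p}, \code{effect_liability} (least-squares slope of
#'   \eqn{\hat\epsilon} on dosage), \code{se}, \code{or}, \code{defined}.
#' @export
ltTest <- function(pm, geno, nuisance = NULL, imputeDosage = FALSE,
                   model = NULL) {
  D <- dosages(geno)                      # samples x SNPs
  common <- intersect(pm@sampleIds, rownames(D))
  if (!length(common)) stop("no overlapping samples between pm and genotypes")
  D <- D[common, , drop = FALSE]
  eps <- pm@posteriorMean[match(common, pm@sampleIds)]
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (!is.null(rownames(nuisance))) {
      if (!all(common %in% rownames(nuisance)))
        stop("nuisance matrix lacks some samples")
      nuisance <- nuisance[common, , drop = FALSE]
    } else if (nrow(nuisance) == length(pm@sampleIds)) {
      nuisance <- nuisance[match(common, pm@sampleIds), , drop = FALSE]
    } else stop("nuisance rows must match samples")
    if (qr(cbind(1, nuisance))$rank < ncol(nuisance) + 1L)
      stop("singular nuisance design")
  }
  info <- snpInfo(geno)
  out <- lapply(seq_len(ncol(D)), function(j) {
    g <- D[, j]
    y <- eps
    if (anyNA(g)) {
      if (imputeDosage) {
        g[is.na(g)] <- mean(g, na.rm = TRUE)
      } else {
        keep <- !is.na(g)
        g <- g[keep]; y <- y[keep]
      }
    }
    Z <- if (is.null(nuisance)) NULL else {
      zz <- nuisance
      if (nrow(zz) != length(g)) zz <- zz[!is.na(D[, j]), , drop = FALSE]
      zz
    }
    n <- length(g)
    af <- mean(g) / 2
    K <- if (is.null(Z)) 0L else ncol(Z)
    if (n < K + 3L || var(g) == 0 || var(y) == 0)
      return(data.frame(n = n, af = af, statistic = NA_real_, p = NA_real_,
                        effect_liability = NA_real_, se = NA_real_,
                        defined = FALSE))
    if (!is.null(Z)) {
      g <- stats::lm.fit(cbind(1, Z), g)$residuals
      y <- stats::lm.fit(cbind(1, Z), y)$residuals
      if (var(g) == 0 || var(y) == 0)
        return(data.frame(n = n, af = af, statistic = NA_real_, p = NA_real_,
                          effect_liability = NA_real_, se = NA_real_,
                          defined = FALSE))
    }
    r2 <- cor(g, y)^2
    stat <- (n - K - ifelse(K > 0, 1, 0)) * r2
    gc <- g - mean(g); yc <- y - mean(y)
    b <- sum(gc * yc) / sum(gc^2)
    df <- n - K - 2L
    s2 <- (sum(yc^2) - b * sum(gc * yc)) / df
    data.frame(n = n, af = af, statistic = stat,
               p = pchisq(stat, 1L, lower.tail = FALSE),
               effect_liability = b, se = sqrt(s2 / sum(gc^2)),
               defined = TRUE)
  })
  res <- do.call(rbind, out)
  res <- cbind(data.frame(snp_id = info$snp_id, chr = info$chr,
                          pos = info$pos), res)
  res$or <- NA_real_
  if (!is.null(model)) {
    ok <- res$defined & res$af > 0 & res$af < 1
    res$or[ok] <- vapply(which(ok), function(i)
      liabilityEffectToOR(model, res$effect_liability[i], res$af[i]), 0)
  }
  rownames(res) <- NULL
  res
}

#' Convert a liability-scale effect to a per-allele odds ratio
#'
#' Model-implied per-allele odds ratio at given covariate values: the
#' case and control genotype distributions implied by the LT model with
#' the stated effect are computed
#' (\code{\link{stratumGenotypeDistribution}}), and the odds ratio is the
#' exponentiated slope of a logistic fit of status on allele count over
#' the expected genotype frequencies. Case and control distributions are
#' evaluated at the same covariate values; this is an approximation whose
#' value depends on the chosen covariate stratum (odds ratios under the
#' LT model are not covariate-invariant).
#'
#' @param model a \linkS4class{LiabilityModel}.
#' @param effect per-allele effect on the liability scale.
#' @param maf population frequency of the counted allele, in (0, 1).
#' @param at optional covariate values at which to evaluate (default: the
#'   model's reference means).
#' @return The per-allele odds ratio.
#' @examples
#' t2d <- LiabilityModel(c(BMI = 0.08), 26.5, -1.44)
#' liabilityEffectToOR(t2d, 0.1, 0.5, at = 24)   # ~1.24
#' @export
liabilityEffectToOR <- function(model, effect, maf, at = NULL) {
  if (!is.finite(maf) || maf <= 0 || maf >= 1)
    stop("maf must lie strictly in (0, 1)")
  if (effect == 0) return(1)
  if (is.null(at)) at <- model@referenceMeans
  pc <- stratumGenotypeDistribution(model, at, "case", effect, maf)$probabilities
  pn <- stratumGenotypeDistribution(model, at, "control", effect, maf)$probabilities
  d <- data.frame(g = rep(0:2, 2L), z = rep(c(1, 0), each = 3L),
                  w = c(pc, pn))
  fit <- glm(z ~ g, family = stats::quasibinomial(), weights = w, data = d)
  unname(exp(coef(fit)[2L]))
}

#' Convert a chi-square statistic between degrees of freedom
#'
#' Maps a statistic to the value with the same upper-tail probability
#' under a different degrees-of-freedom; used to report 2-dof joint tests
#' on the 1-dof scale. Computed in log tail space so genome-wide-scale
#' statistics convert without underflow.
#'
#' @param value nonnegative chi-square statistic(s).
#' @param fromDf,toDf degrees of freedom (>= 1).
#' @return The converted statistic(s).
#' @export
chisqDfConvert <- function(value, fromDf, toDf) {
  if (any(value < 0)) stop("chi-square statistics must be nonnegative")
  if (fromDf == toDf) return(value)
  lp <- pchisq(value, fromDf, lower.tail = FALSE, log.p = TRUE)
  qchisq(lp, toDf, lower.tail = FALSE, log.p = TRUE)
}

#' Fixed-effect inverse-variance meta-analysis
#'
#' Standard inverse-variance-weighted combination of per-study effects
#' (e.g. liability-scale effects from \code{\link{ltTest}} across
#' cohorts).
#'
#' @param effects per-study effect estimates.
#' @param stderrs per-study standard errors (> 0).
#' @return list with \code{effect}, \code{se}, \code{statistic} (1-dof
#'   chi-square) and \code{p}.
#' @export
metaCombine <- function(effects, stderrs) {
  if (length(effects) != length(stderrs) || !length(effects))
    stop("effects and stderrs must have equal, nonzero length")
  if (any(!is.finite(stderrs) | stderrs <= 0))
    stop("standard errors must be positive")
  w <- 1 / stderrs^2
  eff <- sum(w * effects) / sum(w)
  se <- sqrt(1 / sum(w))
  stat <- (eff / se)^2
  list(effect = eff, se = se, statistic = stat,
       p = pchisq(stat, 1L, lower.tail = FALSE))
}
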