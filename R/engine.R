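# Vectorized replicate engine for stratified case-control-covariate
# designs. Replicate datasets collapse to stratum x genotype count tables,
# so every statistic is computed from aggregated counts: the LT trend
# statistic in closed form, the logistic-family tests by small Newton
# solves vectorized across replicates.

.log1pexp <- function(x) {
  out <- x
  lo <- x <= 18
  out[lo] <- log1p(exp(x[lo]))
  hi <- !lo & x <= 33
  out[hi] <- x[hi] + exp(-x[hi])
  out
}

# Vectorized 2-parameter logistic fit on 3 genotype cells.
# y, m: R x 3 matrices of successes / totals; x: the 3 cell scores.
# Returns log-likelihood (up to the binomial constant), the slope, its
# model-based variance, and the intercept, one per replicate row.
.vecLogit2 <- function(y, m, x = 0:2, maxit = 30L, tol = 1e-10) {
  R <- nrow(y)
  Y <- rowSums(y); M <- rowSums(m)
  phat <- pmin(pmax(Y / M, 1e-12), 1 - 1e-12)
  a <- log(phat / (1 - phat)); b <- numeric(R)
  X <- matrix(x, R, 3L, byrow = TRUE)
  for (it in seq_len(maxit)) {
    eta <- a + b * X
    mu <- plogis(eta)
    w <- m * mu * (1 - mu)
    r <- y - m * mu
    U1 <- rowSums(r); U2 <- rowSums(X * r)
    I11 <- rowSums(w); I12 <- rowSums(X * w); I22 <- rowSums(X^2 * w)
    det <- I11 * I22 - I12^2
    det[det < 1e-300] <- NA
    da <- (I22 * U1 - I12 * U2) / det
    db <- (I11 * U2 - I12 * U1) / det
    da[is.na(da)] <- 0; db[is.na(db)] <- 0
    a <- a + da; b <- b + db
    if (max(abs(da), abs(db)) < tol) break
  }
  eta <- a + b * X
  ll <- rowSums(y * eta - m * .log1pexp(eta))
  eta0 <- ifelse(M > 0, log(pmax(Y, 0.5)) - log(pmax(M - Y, 0.5)), 0)
  ll0 <- Y * log(pmax(Y / M, 1e-300)) + (M - Y) * log(pmax(1 - Y / M, 1e-300))
  mu <- plogis(eta); w <- m * mu * (1 - mu)
  I11 <- rowSums(w); I12 <- rowSums(X * w); I22 <- rowSums(X^2 * w)
  varb <- I11 / pmax(I11 * I22 - I12^2, 1e-300)
  list(ll = ll, ll0 = ll0, lrt = 2 * (ll - ll0), b = b, varb = varb)
}

# Vectorized 3-parameter logistic fit (intercept, genotype, covariate) on
# C cells; xg, xt: cell scores (length C); y, m: R x C.
.vecLogit3 <- function(y, m, xg, xt, maxit = 40L, tol = 1e-10) {
  R <- nrow(y); C <- ncol(y)
  Y <- rowSums(y); M <- rowSums(m)
  phat <- pmin(pmax(Y / M, 1e-12), 1 - 1e-12)
  a <- log(phat / (1 - phat)); b <- numeric(R); cc <- numeric(R)
  Xg <- matrix(xg, R, C, byrow = TRUE)
  Xt <- matrix(xt, R, C, byrow = TRUE)
  for (it in seq_len(maxit)) {
    eta <- a + b * Xg + cc * Xt
    mu <- plogis(eta)
    w <- m * mu * (1 - mu)
    r <- y - m * mu
    U1 <- rowSums(r); U2 <- rowSums(Xg * r); U3 <- rowSums(Xt * r)
    A <- rowSums(w);       B <- rowSums(Xg * w);     D <- rowSums(Xt * w)
    E <- rowSums(Xg^2 * w); F <- rowSums(Xg * Xt * w); G <- rowSums(Xt^2 * w)
    # symmetric 3x3 [[A,B,D],[B,E,F],[D,F,G]] solved by cofactors
    c11 <- E * G - F^2; c12 <- D * F - B * G; c13 <- B * F - D * E
    c22 <- A * G - D^2; c23 <- B * D - A * F; c33 <- A * E - B^2
    det <- A * c11 + B * c12 + D * c13
    det[abs(det) < 1e-300] <- NA
    da <- (c11 * U1 + c12 * U2 + c13 * U3) / det
    db <- (c12 * U1 + c22 * U2 + c23 * U3) / det
    dc <- (c13 * U1 + c23 * U2 + c33 * U3) / det
    da[is.na(da)] <- 0; db[is.na(db)] <- 0; dc[is.na(dc)] <- 0
    a <- a + da; b <- b + db; cc <- cc + dc
    if (max(abs(da), abs(db), abs(dc)) < tol) break
  }
  eta <- a + b * Xg + cc * Xt
  ll <- rowSums(y * eta - m * .log1pexp(eta))
  # null model: intercept + covariate (no genotype)
  a0 <- a; c0 <- cc
  for (it in seq_len(maxit)) {
    eta <- a0 + c0 * Xt
    mu <- plogis(eta)
    w <- m * mu * (1 - mu)
    r <- y - m * mu
    U1 <- rowSums(r); U3 <- rowSums(Xt * r)
    I11 <- rowSums(w); I13 <- rowSums(Xt * w); I33 <- rowSums(Xt^2 * w)
    det <- I11 * I33 - I13^2
    det[det < 1e-300] <- NA
    da <- (I33 * U1 - I13 * U3) / det
    dc <- (I11 * U3 - I13 * U1) / det
    da[is.na(da)] <- 0; dc[is.na(dc)] <- 0
    a0 <- a0 + da; c0 <- c0 + dc
    if (max(abs(da), abs(dc)) < tol) break
  }
  eta0 <- a0 + c0 * Xt
  ll0 <- rowSums(y * eta0 - m * .log1pexp(eta0))
  list(ll = ll, ll0 = ll0, lrt = 2 * (ll - ll0), b = b)
}

# Draw stratum x genotype counts for R replicates: list (per stratum) of
# R x 3 matrices. Multinomial via sequential binomials, vectorized.
.drawStratumCounts <- function(probs, counts, R, hweApprox = FALSE) {
  S <- nrow(probs)
  lapply(seq_len(S), function(s) {
    n <- counts[s]; p <- probs[s, ]
    if (hweApprox) {
      af <- (p[2L] + 2 * p[3L]) / 2
      # n individuals each Binomial(2, af): cell counts from two binomials
      n2 <- rbinom(R, n, af^2)
      n1 <- rbinom(R, n - n2, 2 * af * (1 - af) / (1 - af^2))
      cbind(n - n1 - n2, n1, n2)
    } else {
      n2 <- rbinom(R, n, p[3L])
      n1 <- rbinom(R, n - n2, p[2L] / (p[1L] + p[2L]))
      cbind(n - n1 - n2, n1, n2)
    }
  })
}

.engineTests <- c("lt", "logr", "logr_cov", "g_gxe", "gxe", "logr_sub",
                  "case_only")

# Per-test chi-square(1-dof scale) and p-values from stratum counts.
# cnt: list of R x 3 matrices; strata: design strata (single covariate).
.statsFromCounts <- function(cnt, strata, eps, tests, covName) {
  R <- nrow(cnt[[1L]])
  S <- length(cnt)
  g <- 0:2
  caseIdx <- which(strata$status == 1L)
  ctrlIdx <- which(strata$status == 0L)
  tvals <- strata[[covName]]
  out <- list()
  sumCells <- function(idx) Reduce(`+`, cnt[idx])
  if ("lt" %in% tests) {
    N <- sum(strata$count)
    Sg <- 0; Sg2 <- 0; Sge <- 0
    for (s in seq_len(S)) {
      rs <- cnt[[s]] %*% g
      Sg <- Sg + rs
      Sg2 <- Sg2 + cnt[[s]] %*% (g^2)
      Sge <- Sge + rs * eps[s]
    }
    Se <- sum(strata$count * eps)
    Se2 <- sum(strata$count * eps^2)
    vg <- Sg2 - Sg^2 / N
    ve <- Se2 - Se^2 / N
    covge <- Sge - Sg * Se / N
    stat <- as.numeric(N * covge^2 / (vg * ve))
    stat[!is.finite(stat)] <- NA
    out$lt <- list(stat = stat, p = pchisq(stat, 1L, lower.tail = FALSE))
  }
  needCase <- sumCells(caseIdx)
  needAll <- sumCells(seq_len(S))
  if ("logr" %in% tests) {
    f <- .vecLogit2(needCase, needAll)
    out$logr <- list(stat = f$lrt, p = pchisq(f$lrt, 1L, lower.tail = FALSE))
  }
  lv <- sort(unique(tvals))
  if (any(c("logr_cov", "gxe") %in% tests)) {
    # cells: (covariate level, genotype)
    yC <- do.call(cbind, lapply(lv, function(v)
      sumCells(intersect(caseIdx, which(tvals == v)))))
    mC <- do.call(cbind, lapply(lv, function(v)
      sumCells(which(tvals == v))))
    xg <- rep(g, length(lv)); xt <- rep(lv, each = 3L)
    f3 <- .vecLogit3(yC, mC, xg, xt)
    out$logr_cov <- list(stat = f3$lrt,
                         p = pchisq(f3$lrt, 1L, lower.tail = FALSE))
  }
  if (any(c("g_gxe", "gxe") %in% tests)) {
    if (length(lv) != 2L)
      stop("g_gxe fast path needs a two-level covariate")
    lrt2 <- 0
    for (v in lv) {
      yv <- sumCells(intersect(caseIdx, which(tvals == v)))
      mv <- sumCells(which(tvals == v))
      lrt2 <- lrt2 + .vecLogit2(yv, mv)$lrt
    }
    if ("g_gxe" %in% tests)
      out$g_gxe <- list(stat = chisqDfConvert(lrt2, 2L, 1L),
                        p = pchisq(lrt2, 2L, lower.tail = FALSE))
    if ("gxe" %in% tests) {
      stat <- pmax(lrt2 - out$logr_cov$stat, 0)
      out$gxe <- list(stat = stat, p = pchisq(stat, 1L, lower.tail = FALSE))
    }
  }
  if ("logr_sub" %in% tests) {
    cutoff <- mean(range(tvals[caseIdx]))
    lowCase <- intersect(caseIdx, which(tvals <= cutoff))
    f <- .vecLogit2(sumCells(lowCase),
                    sumCells(lowCase) + sumCells(ctrlIdx))
    out$logr_sub <- list(stat = f$lrt,
                         p = pchisq(f$lrt, 1L, lower.tail = FALSE))
  }
  if ("case_only" %in% tests) {
    cutoff <- mean(range(tvals[caseIdx]))
    lowCase <- intersect(caseIdx, which(tvals <= cutoff))
    f <- .vecLogit2(sumCells(lowCase), needCase)
    out$case_only <- list(stat = f$lrt,
                          p = pchisq(f$lrt, 1L, lower.tail = FALSE))
  }
  out[tests]
}

#' Replicate summary from the simulation engine
#'
#' @slot stats data.frame: per test the mean 1-dof chi-square, its Monte
#'   Carlo standard error, and the replicate count.
#' @slot power data.frame: per (test, alpha) the exceedance fraction
#'   P(p < alpha) with binomial standard error.
#' @slot nReplicates replicate count.
#' @slot statistics per-replicate 1-dof-scale statistics (replicates x
#'   tests), retained only when requested.
#' @slot pvalues per-replicate p-values, likewise.
#' @export
setClass("ReplicateSummary",
  representation(stats = "data.frame", power = "data.frame",
                 nReplicates = "integer", statistics = "matrix",
                 pvalues = "matrix"))

setMethod("show", "ReplicateSummary", function(object) {
  cat(sprintf("ReplicateSummary over %d replicates\n", object@nReplicates))
  print(object@stats, row.names = FALSE, digits = 4)
  if (nrow(object@power)) {
    cat("power:\n")
    print(object@power, row.names = FALSE, digits = 4)
  }
})

#' Accessors for ReplicateSummary
#' @param x a \linkS4class{ReplicateSummary}.
#' @export
replicateStats <- function(x) x@stats

#' @rdname replicateStats
#' @export
replicatePower <- function(x) x@power

#' @rdname replicateStats
#' @export
replicateStatistics <- function(x) x@statistics

#' Run the replicate power study
#'
#' Simulates \code{nReplicates} datasets under the design and computes the
#' requested statistics per replicate, accumulating mean chi-square values
#' with Monte Carlo standard errors and exceedance fractions (power) at
#' the given significance thresholds. Joint 2-dof statistics are reported
#' on the equivalent 1-dof scale; their p-values use the 2-dof tail.
#'
#' For stratified (case-control-covariate) designs with a single clinical
#' covariate the engine is fully vectorized: replicates collapse to
#' stratum x genotype count tables, the LT trend statistic is computed in
#' closed form and the logistic-family tests by Newton solves vectorized
#' across replicates. Other designs fall back to per-replicate dataset
#' simulation and the reference per-dataset test functions (much slower;
#' intended for small calibration runs). Results are deterministic given
#' (design, seed).
#'
#' @param design a \linkS4class{SimDesign}.
#' @param tests subset of \code{c("lt", "logr", "logr_cov", "g_gxe",
#'   "gxe", "logr_sub", "case_only")}.
#' @param alphas significance thresholds for the power tabulation.
#' @param nReplicates,seed override the design's defaults.
#' @param analysisModel \linkS4class{LiabilityModel} used to compute the
#'   posterior mean liabilities entering the LT statistic (default: the
#'   design's generative model); supplying a different model measures
#'   robustness to parameter mis-specification.
#' @param hweApprox draw stratum genotypes binomially at the stratum
#'   allele frequency instead of the exact conditional distribution.
#' @param keepStatistics retain the per-replicate statistic and p-value
#'   matrices (needed e.g. for distributional checks).
#' @return A \linkS4class{ReplicateSummary}.
#' @examples
#' d <- toyT2DDesign(gamma = 0.1)
#' runReplicates(d, tests = c("lt", "logr"), nReplicates = 2000, seed = 7)
#' @export
runReplicates <- function(design, tests = c("lt", "logr"),
                          alphas = c(0.05, 5e-8),
                          nReplicates = design@nReplicates,
                          seed = design@seed, hweApprox = FALSE,
                          keepStatistics = FALSE, analysisModel = NULL) {
  if (is.null(analysisModel)) analysisModel <- design@model
  tests <- match.arg(tests, .engineTests, several.ok = TRUE)
  R <- as.integer(nReplicates)
  if (R < 1L) stop("need at least one replicate")
  st <- design@strata
  covCols <- .covariateColumns(st)
  fast <- design@ascertainment == "case_control_covariate" &&
    length(covCols) == 1L
  set.seed(seed)
  if (fast) {
    covName <- covCols
    probs <- t(vapply(seq_len(nrow(st)), function(i)
      .stratumProbs(design, st[i, covCols, drop = FALSE], st$status[i]),
      numeric(3L)))
    # posterior means per stratum under the analysis (liability) model
    miniCohort <- LTCohort(paste0("st", seq_len(nrow(st))), st$status,
                           matrix(st[[covName]], ncol = 1L,
                                  dimnames = list(NULL, covName)))
    eps <- posteriorMeans(analysisModel, miniCohort)@posteriorMean
    cnt <- .drawStratumCounts(probs, st$count, R, hweApprox)
    res <- .statsFromCounts(cnt, st, eps, tests, covName)
    statM <- do.call(cbind, lapply(res, `[[`, "stat"))
    pM <- do.call(cbind, lapply(res, `[[`, "p"))
    colnames(statM) <- colnames(pM) <- tests
  } else {
    statM <- matrix(NA_real_, R, length(tests),
                    dimnames = list(NULL, tests))
    pM <- statM
    seeds <- sample.int(.Machine$integer.max, R)
    for (r in seq_len(R)) {
      sim <- simulateDataset(design, seed = seeds[r], hweApprox = hweApprox)
      z <- caseStatus(sim$cohort)
      gvec <- dosages(sim$genotypes)[, 1L]
      X <- covariateValues(sim$cohort)
      x1 <- if (ncol(X)) X[, 1L] else NULL
      for (tn in tests) {
        v <- switch(tn,
          lt = {
            pm <- posteriorMeans(analysisModel, sim$cohort)
            row <- ltTest(pm, sim$genotypes)
            list(stat = row$statistic, p = row$p)
          },
          logr = { f <- logrTest(z, gvec); list(stat = f$statistic, p = f$p) },
          logr_cov = {
            f <- logrTest(z, gvec, covariates = x1)
            list(stat = f$statistic, p = f$p)
          },
          g_gxe = {
            f <- gGxeTest(z, gvec, x1)
            list(stat = f$statistic1dof, p = f$p)
          },
          gxe = {
            f <- gxe1dofTest(z, gvec, x1)
            list(stat = f$statistic, p = f$p)
          },
          logr_sub = {
            f <- logrSubsetTest(z, gvec, x1, cutoff = mean(range(x1[z == 1])))
            list(stat = f$statistic, p = f$p)
          },
          case_only = {
            grp <- x1[z == 1] <= mean(range(x1[z == 1]))
            f <- caseOnlyTest(as.integer(grp), gvec[z == 1])
            list(stat = f$statistic, p = f$p)
          })
        statM[r, tn] <- v$stat
        pM[r, tn] <- v$p
      }
    }
  }
  stats <- data.frame(
    test = tests,
    meanChisq = colMeans(statM, na.rm = TRUE),
    mcse = apply(statM, 2L, function(x) stats::sd(x, na.rm = TRUE)) /
      sqrt(colSums(!is.na(statM))),
    nReplicates = R)
  power <- do.call(rbind, lapply(alphas, function(a) {
    frac <- colMeans(pM < a, na.rm = TRUE)
    data.frame(test = tests, alpha = a, power = frac,
               se = sqrt(frac * (1 - frac) / R))
  }))
  rownames(stats) <- rownames(power) <- NULL
  new("ReplicateSummary", stats = stats, power = power, nReplicates = R,
      statistics = if (keepStatistics) statM else
        matrix(numeric(0), 0L, 0L),
      pvalues = if (keepStatistics) pM else matrix(numeric(0), 0L, 0L))
}
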