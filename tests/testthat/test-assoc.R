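# helpers to wrap plain vectors into the S4 containers
.wrapPm <- function(eps) {
  n <- length(eps)
  methods::new("PosteriorLiability", sampleIds = sprintf("s%03d", 1:n),
               threshold = rep(0, n), posteriorMean = as.numeric(eps),
               mode = rep("tail", n))
}
.wrapGeno <- function(g) {
  n <- length(g)
  GenotypeMatrix(matrix(as.numeric(g), n, 1,
                        dimnames = list(sprintf("s%03d", 1:n), "snp")))
}

test_that("LT statistic equals the score test on random data", {
  set.seed(5150)
  for (i in 1:200) {
    n <- sample(20:80, 1)
    g <- rbinom(n, 2, runif(1, 0.15, 0.85))
    if (var(g) == 0) next
    eps <- rnorm(n)
    res <- ltTest(.wrapPm(eps), .wrapGeno(g))
    gc <- g - mean(g)
    U <- sum(gc * eps)
    score <- U^2 / (sum(gc^2) * sum((eps - mean(eps))^2) / n)
    expect_equal(res$statistic, score, tolerance = 1e-10)
  }
})

test_that("degenerate posterior means reduce to the Armitage trend test", {
  set.seed(99)
  g <- rbinom(120, 2, 0.4)
  z <- rbinom(120, 1, 0.5)
  res <- ltTest(.wrapPm(z), .wrapGeno(g))
  tab <- table(factor(z, 0:1), factor(g, 0:2))
  oracle <- prop.trend.test(tab[2, ], colSums(tab), score = 0:2)
  expect_equal(res$statistic, unname(oracle$statistic), tolerance = 1e-8)
})

test_that("toy design at exact expected moments gives chi-square near 30.3", {
  t2d <- t2dModel()
  strata <- data.frame(status = c(1, 1, 0, 0), BMI = c(24, 35, 24, 35))
  probs <- t(mapply(function(t, z) stratumGenotypeDistribution(
    t2d, t, if (z == 1) "case" else "control", 0.1, 0.5)$probabilities,
    strata$BMI, strata$status))
  co <- LTCohort(paste0("s", 1:4), strata$status, cbind(BMI = strata$BMI))
  eps <- posteriorMean(posteriorMeans(t2d, co))
  # N * r^2 on the expected stratum x genotype counts (4 x 1500 samples)
  cnt <- 1500 * probs
  g <- 0:2; N <- sum(cnt)
  Sg <- sum(t(cnt) * g); Sg2 <- sum(t(cnt) * g^2)
  Se <- sum(rowSums(cnt) * eps); Se2 <- sum(rowSums(cnt) * eps^2)
  Sge <- sum(cnt %*% g * eps)
  stat <- N * (Sge - Sg * Se / N)^2 /
    ((Sg2 - Sg^2 / N) * (Se2 - Se^2 / N))
  expect_equal(stat, 30.3, tolerance = 0.01)
})

test_that("statistic is invariant to affine rescaling of posterior means", {
  set.seed(12)
  g <- rbinom(200, 2, 0.3)
  eps <- rnorm(200)
  s1 <- ltTest(.wrapPm(eps), .wrapGeno(g))$statistic
  s2 <- ltTest(.wrapPm(3.7 * eps - 11), .wrapGeno(g))$statistic
  expect_equal(s1, s2, tolerance = 1e-10)
})

test_that("nuisance covariates residualize both sides (EIGENSTRAT form)", {
  set.seed(31)
  n <- 150
  pcs <- matrix(rnorm(2 * n), n, 2)
  g <- rbinom(n, 2, 0.4) + 0.3 * pcs[, 1]
  g <- pmin(pmax(g, 0), 2)
  eps <- rnorm(n) + 0.5 * pcs[, 2]
  res <- ltTest(.wrapPm(eps), .wrapGeno(g), nuisance = pcs)
  rg <- resid(lm(g ~ pcs))
  re <- resid(lm(eps ~ pcs))
  expect_equal(res$statistic, (n - 2 - 1) * cor(rg, re)^2,
               tolerance = 1e-10)
  expect_error(ltTest(.wrapPm(eps), .wrapGeno(g),
                      nuisance = cbind(pcs[, 1], pcs[, 1])), "singular")
})

test_that("missing genotypes: complete-case by default, optional imputation", {
  set.seed(44)
  g <- rbinom(100, 2, 0.5)
  eps <- rnorm(100)
  full <- ltTest(.wrapPm(eps), .wrapGeno(g))
  gm <- g; gm[c(3, 50)] <- NA
  cc <- ltTest(.wrapPm(eps), .wrapGeno(gm))
  expect_equal(cc$n, 98)
  expect_equal(cc$statistic,
               ltTest(.wrapPm(eps[-c(3, 50)]),
                      .wrapGeno(g[-c(3, 50)]))$statistic)
  imp <- ltTest(.wrapPm(eps), .wrapGeno(gm), imputeDosage = TRUE)
  expect_equal(imp$n, 100)
  # no missingness: both policies identical
  expect_equal(full$statistic,
               ltTest(.wrapPm(eps), .wrapGeno(g),
                      imputeDosage = TRUE)$statistic)
})

test_that("monomorphic SNPs are flagged undefined, not zero", {
  eps <- rnorm(50)
  res <- ltTest(.wrapPm(eps), .wrapGeno(rep(2, 50)))
  expect_false(res$defined)
  expect_true(is.na(res$statistic))
})

test_that("chi-square df conversion preserves tail probability", {
  expect_equal(chisqDfConvert(7.3, 2, 2), 7.3)
  q2 <- qchisq(0.05, 2, lower.tail = FALSE)       # 5.991
  expect_equal(chisqDfConvert(q2, 2, 1),
               qchisq(0.05, 1, lower.tail = FALSE), tolerance = 1e-10)
  expect_equal(chisqDfConvert(0, 2, 1), 0)
  big <- chisqDfConvert(300, 2, 1)
  expect_true(is.finite(big) && big > 250)
  expect_error(chisqDfConvert(-1, 2, 1), "nonnegative")
})

test_that("inverse-variance meta-analysis matches the weighted-mean oracle", {
  one <- metaCombine(0.12, 0.03)
  expect_equal(one$effect, 0.12)
  expect_equal(one$se, 0.03)
  two <- metaCombine(c(0.2, 0.2), c(0.05, 0.05))
  expect_equal(two$effect, 0.2)
  expect_equal(two$se, 0.05 / sqrt(2))
  b <- c(0.1, -0.05, 0.3); s <- c(0.02, 0.05, 0.1)
  mc <- metaCombine(b, s)
  w <- 1 / s^2
  expect_equal(mc$effect, sum(w * b) / sum(w), tolerance = 1e-12)
  expect_equal(mc$se, sqrt(1 / sum(w)), tolerance = 1e-12)
  expect_error(metaCombine(c(1, 2), c(0.1, 0)), "positive")
})

test_that("liability effects convert to plausible odds ratios", {
  t2d <- t2dModel()
  expect_equal(liabilityEffectToOR(t2d, 0, 0.5), 1)
  or24 <- liabilityEffectToOR(t2d, 0.1, 0.5, at = 24)
  expect_gt(or24, 1.24); expect_lt(or24, 1.25)
  or35 <- liabilityEffectToOR(t2d, 0.1, 0.5, at = 35)
  expect_lt(or35, or24)   # higher covariate contribution, weaker OR
  # independent maximizer oracle on the same expected genotype counts
  pc <- stratumGenotypeDistribution(t2d, 24, "case", 0.1, 0.5)$probabilities
  pn <- stratumGenotypeDistribution(t2d, 24, "control", 0.1,
                                    0.5)$probabilities
  nll <- function(par) {
    eta <- par[1] + par[2] * 0:2
    -sum(pc * (eta - log1p(exp(eta))) + pn * (-log1p(exp(eta))))
  }
  opt <- optim(c(0, 0), nll, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 2000))
  expect_equal(log(or24), opt$par[2], tolerance = 1e-4)
})
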