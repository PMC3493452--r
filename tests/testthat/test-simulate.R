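test_that("design validation catches inconsistent inputs", {
  m <- t2dModel()
  expect_error(SimDesign(m, maf = 0, strata = data.frame(count = 1)),
               "maf")
  expect_error(SimDesign(m, strata = data.frame(BMI = 24, count = -1)),
               "positive")
  expect_error(SimDesign(m, strata = data.frame(BMI = 24, count = 10)),
               "status")
  expect_error(SimDesign(m, generator = "logit",
                         strata = data.frame(status = 1, BMI = 24,
                                             count = 10)),
               "logitParams")
})

test_that("identical (design, seed) gives byte-identical datasets", {
  d <- toyT2DDesign(gamma = 0.08, nPerStratum = 200L)
  a <- simulateDataset(d, seed = 123)
  b <- simulateDataset(d, seed = 123)
  expect_identical(dosages(a$genotypes), dosages(b$genotypes))
  expect_identical(caseStatus(a$cohort), caseStatus(b$cohort))
  c <- simulateDataset(d, seed = 124)
  expect_false(identical(dosages(a$genotypes), dosages(c$genotypes)))
  s1 <- runReplicates(d, nReplicates = 500, seed = 9)
  s2 <- runReplicates(d, nReplicates = 500, seed = 9)
  expect_identical(replicateStats(s1), replicateStats(s2))
})

test_that("null genotypes are Hardy-Weinberg at the population frequency", {
  d <- toyT2DDesign(gamma = 0, nPerStratum = 20000L)
  sim <- simulateDataset(d, seed = 31)
  g <- dosages(sim$genotypes)[, 1]
  af <- mean(g) / 2
  expect_lt(abs(af - 0.5), 3 * sqrt(0.25 / (2 * length(g))))
})

test_that("stratified sampling reproduces the toy stratum allele frequency", {
  d <- toyT2DDesign(gamma = 0.1, nPerStratum = 50000L)
  sim <- simulateDataset(d, seed = 32)
  z <- caseStatus(sim$cohort)
  bmi <- covariateValues(sim$cohort)[, "BMI"]
  g <- dosages(sim$genotypes)[, 1]
  af <- mean(g[z == 1 & bmi == 24]) / 2
  expect_equal(round(af, 2), 0.55)
  af35 <- mean(g[z == 0 & bmi == 35]) / 2
  expect_equal(round(af35, 2), 0.49)
})

test_that("random ascertainment reproduces the model prevalence", {
  d <- SimDesign(t2dModel(), gamma = 0, ascertainment = "random",
                 strata = data.frame(BMI = 26.5, count = 20000))
  sim <- simulateDataset(d, seed = 33)
  frac <- mean(caseStatus(sim$cohort))
  K <- pnorm(-1.44)   # ~0.075
  expect_lt(abs(frac - K), 3 * sqrt(K * (1 - K) / 20000))
})

test_that("case-control rejection sampling hits its targets", {
  d <- SimDesign(t2dModel(), gamma = 0.1, ascertainment = "case_control",
                 strata = data.frame(BMI = c(24, 35), count = c(1, 1)),
                 nCases = 400L, nControls = 500L)
  sim <- simulateDataset(d, seed = 34)
  expect_equal(sum(caseStatus(sim$cohort) == 1), 400)
  expect_equal(sum(caseStatus(sim$cohort) == 0), 500)
  # cases are enriched for the risk allele and for high BMI
  z <- caseStatus(sim$cohort)
  g <- dosages(sim$genotypes)[, 1]
  expect_gt(mean(g[z == 1]), mean(g[z == 0]))
})

test_that("logit generator behaves like its logistic model", {
  # all zero log-odds: everyone has case probability one half
  d0 <- SimDesign(LiabilityModel(affine = -1), generator = "logit",
                  logitParams = list(intercept = 0, genotype = 0),
                  ascertainment = "random",
                  strata = data.frame(count = 4000))
  sim0 <- simulateDataset(d0, seed = 35)
  expect_lt(abs(mean(caseStatus(sim0$cohort)) - 0.5),
            3 * sqrt(0.25 / 4000))
  # case-control sampling preserves the genotype log odds ratio
  d1 <- SimDesign(LiabilityModel(affine = -1), generator = "logit",
                  logitParams = list(intercept = -2, genotype = 0.4),
                  ascertainment = "case_control",
                  strata = data.frame(count = 1),
                  nCases = 1500L, nControls = 1500L)
  sim1 <- simulateDataset(d1, seed = 36)
  fit <- logrTest(caseStatus(sim1$cohort), dosages(sim1$genotypes)[, 1])
  expect_lt(abs(fit$logOr - 0.4), 4 * fit$se)
})

test_that("vectorized logistic fitters match glm on aggregated counts", {
  set.seed(71)
  for (i in 1:20) {
    m <- matrix(rpois(3, 80) + 5, 1, 3)
    y <- matrix(rbinom(3, m, runif(3, 0.2, 0.8)), 1, 3)
    f <- ltassoc:::.vecLogit2(y, m)
    d <- data.frame(g = 0:2, y = y[1, ], n = m[1, ])
    g1 <- glm(cbind(y, n - y) ~ g, family = binomial(), data = d)
    g0 <- glm(cbind(y, n - y) ~ 1, family = binomial(), data = d)
    expect_equal(f$lrt[1], g0$deviance - g1$deviance, tolerance = 1e-6)
    expect_equal(f$b[1], unname(coef(g1)[2]), tolerance = 1e-6)
  }
  # three-parameter fit on (covariate level, genotype) cells
  for (i in 1:20) {
    m <- matrix(rpois(6, 60) + 5, 1, 6)
    y <- matrix(rbinom(6, m, runif(6, 0.2, 0.8)), 1, 6)
    xg <- rep(0:2, 2); xt <- rep(c(24, 35), each = 3)
    f <- ltassoc:::.vecLogit3(y, m, xg, xt)
    d <- data.frame(g = xg, x = xt, y = y[1, ], n = m[1, ])
    g1 <- glm(cbind(y, n - y) ~ g + x, family = binomial(), data = d)
    g0 <- glm(cbind(y, n - y) ~ x, family = binomial(), data = d)
    expect_equal(f$lrt[1], g0$deviance - g1$deviance, tolerance = 1e-6)
  }
})

test_that("fast engine path agrees with per-dataset reference tests", {
  # one replicate drawn by the slow path, statistics recomputed both ways
  d <- toyT2DDesign(gamma = 0.1, nPerStratum = 400L)
  sim <- simulateDataset(d, seed = 81)
  z <- caseStatus(sim$cohort)
  g <- dosages(sim$genotypes)[, 1]
  bmi <- covariateValues(sim$cohort)[, "BMI"]
  # collapse to stratum x genotype counts and push through the count path
  st <- d@strata
  cnt <- lapply(seq_len(nrow(st)), function(i)
    matrix(tabulate(g[z == st$status[i] & bmi == st$BMI[i]] + 1L, 3L),
           1, 3))
  eps <- posteriorMean(posteriorMeans(
    d@model, LTCohort(paste0("k", 1:4), st$status, cbind(BMI = st$BMI))))
  res <- ltassoc:::.statsFromCounts(
    cnt, st, unname(eps),
    c("lt", "logr", "logr_cov", "g_gxe", "gxe", "logr_sub", "case_only"),
    "BMI")
  pmFull <- posteriorMeans(d@model, sim$cohort)
  expect_equal(res$lt$stat[1], ltTest(pmFull, sim$genotypes)$statistic,
               tolerance = 1e-8)
  expect_equal(res$logr$stat[1], logrTest(z, g)$statistic,
               tolerance = 1e-6)
  expect_equal(res$logr_cov$stat[1],
               logrTest(z, g, covariates = bmi)$statistic,
               tolerance = 1e-6)
  expect_equal(res$g_gxe$stat[1], gGxeTest(z, g, bmi)$statistic1dof,
               tolerance = 1e-6)
  expect_equal(res$gxe$stat[1], gxe1dofTest(z, g, bmi)$statistic,
               tolerance = 1e-5)
  expect_equal(res$logr_sub$stat[1],
               logrSubsetTest(z, g, bmi, cutoff = 29.5)$statistic,
               tolerance = 1e-6)
  grp <- as.integer(bmi[z == 1] <= 29.5)
  expect_equal(res$case_only$stat[1],
               caseOnlyTest(grp, g[z == 1])$statistic, tolerance = 1e-6)
})

test_that("exact-conditional and HWE-binomial sampling agree in mean", {
  d <- toyT2DDesign(gamma = 0.1)
  a <- runReplicates(d, tests = "lt", nReplicates = 5000, seed = 91)
  b <- runReplicates(d, tests = "lt", nReplicates = 5000, seed = 92,
                     hweApprox = TRUE)
  sa <- replicateStats(a); sb <- replicateStats(b)
  expect_lt(abs(sa$meanChisq - sb$meanChisq),
            3 * sqrt(sa$mcse^2 + sb$mcse^2))
})

test_that("power is monotone nondecreasing in the effect size", {
  pw <- vapply(c(0, 0.08, 0.15), function(gam) {
    s <- runReplicates(toyT2DDesign(gamma = gam), tests = "lt",
                       alphas = 0.05, nReplicates = 4000, seed = 93)
    replicatePower(s)$power
  }, 0)
  expect_true(all(diff(pw) >= 0))
})

test_that("null statistics follow the 1-dof chi-square distribution", {
  s <- runReplicates(toyT2DDesign(gamma = 0), tests = "lt",
                     alphas = c(0.05, 0.01), nReplicates = 30000,
                     seed = 94, keepStatistics = TRUE)
  st <- replicateStats(s)
  expect_lt(abs(st$meanChisq - 1), 3 * st$mcse)
  ks <- suppressWarnings(
    ks.test(replicateStatistics(s)[, "lt"], pchisq, df = 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("interaction direction shifts the LT advantage as expected", {
  adv <- vapply(c(-0.01, 0, 0.01), function(delta) {
    s <- runReplicates(toyT2DDesign(gamma = 0.1, interaction = delta),
                       tests = c("lt", "logr"), nReplicates = 15000,
                       seed = 95)
    st <- replicateStats(s)
    st$meanChisq[st$test == "lt"] - st$meanChisq[st$test == "logr"]
  }, 0)
  expect_gt(adv[1], adv[2])   # negative interaction helps LT
  expect_gt(adv[2], adv[3])   # positive interaction hurts LT
  # averaged over +/- interaction the LT statistic still leads
  means <- vapply(c(-0.01, 0.01), function(delta) {
    st <- replicateStats(
      runReplicates(toyT2DDesign(gamma = 0.1, interaction = delta),
                    tests = c("lt", "logr"), nReplicates = 15000,
                    seed = 96))
    c(lt = st$meanChisq[st$test == "lt"],
      logr = st$meanChisq[st$test == "logr"])
  }, c(lt = 0, logr = 0))
  expect_gte(mean(means["lt", ]), mean(means["logr", ]))
})

test_that("slow per-dataset engine path works for unstratified designs", {
  d <- SimDesign(t2dModel(), gamma = 0.15, ascertainment = "case_control",
                 strata = data.frame(BMI = c(24, 35), count = c(1, 1)),
                 nCases = 250L, nControls = 250L)
  s <- runReplicates(d, tests = c("lt", "logr"), nReplicates = 8,
                     seed = 97, keepStatistics = TRUE)
  expect_equal(s@nReplicates, 8L)
  expect_true(all(is.finite(replicateStatistics(s))))
})
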