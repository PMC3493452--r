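test_that("probit-scale fit reproduces the published T2D and prostate models", {
  fitT2D <- fitLTPub(t2dPrevalenceTable())
  expect_equal(round(coef(fitT2D$model)[["BMI"]], 2), 0.08)
  expect_equal(round(affineTerm(fitT2D$model), 2), -1.44)
  # independent ordinary-least-squares oracle on the probit scale
  oracle <- lm(qnorm(c(0.02, 0.03, 0.05, 0.08, 0.13, 0.24)) ~
                 I(c(18, 21.5, 24.5, 27.5, 30.5, 35) - 26.5))
  expect_equal(coef(fitT2D$model)[["BMI"]], unname(coef(oracle)[2]),
               tolerance = 1e-10)
  expect_equal(affineTerm(fitT2D$model), unname(coef(oracle)[1]),
               tolerance = 1e-10)

  fitPr <- fitLTPub(prostatePrevalenceTable())
  expect_equal(round(coef(fitPr$model)[["age"]], 3), 0.049)
  expect_equal(round(affineTerm(fitPr$model), 2), -2.49)
  orP <- lm(qnorm(c(0.02, 0.08, 0.14)) ~ I(c(60, 70, 80) - 50))
  expect_equal(coef(fitPr$model)[["age"]], unname(coef(orP)[2]),
               tolerance = 1e-10)
})

test_that("noiseless two-point data are recovered exactly", {
  m <- LiabilityModel(c(x = 0.07), 10, -2.1)
  K <- predictPrevalence(m, cbind(c(5, 15)))
  fit <- fitLTPub(PrevalenceTable("x", c(5, 15), K, referenceMean = 10))
  expect_equal(coef(fit$model)[["x"]], 0.07, tolerance = 1e-10)
  expect_equal(affineTerm(fit$model), -2.1, tolerance = 1e-10)
  expect_equal(max(abs(fit$residuals)), 0, tolerance = 1e-10)
})

test_that("parameter recovery holds over a (c, m) grid", {
  tvals <- c(20, 24, 28, 32, 36)
  for (c0 in c(0.02, 0.04, 0.06, 0.08, 0.1))
    for (m0 in c(-3, -2, -1)) {
      m <- LiabilityModel(c(x = c0), 28, m0)
      K <- predictPrevalence(m, cbind(tvals))
      fit <- fitLTPub(PrevalenceTable("x", tvals, K, referenceMean = 28))
      expect_equal(coef(fit$model)[["x"]], c0, tolerance = 1e-8)
      expect_equal(affineTerm(fit$model), m0, tolerance = 1e-8)
    }
})

test_that("re-fitting model-implied prevalence is idempotent", {
  fit1 <- fitLTPub(t2dPrevalenceTable())$model
  tvals <- t2dPrevalenceTable()@values
  K2 <- predictPrevalence(fit1, cbind(tvals))
  fit2 <- fitLTPub(PrevalenceTable("BMI", tvals, K2,
                                   referenceMean = 26.5))$model
  expect_equal(coef(fit2), coef(fit1), tolerance = 1e-10)
  expect_equal(affineTerm(fit2), affineTerm(fit1), tolerance = 1e-10)
})

test_that("fit is invariant to reordering and compatible recentering", {
  tb <- t2dPrevalenceTable()
  perm <- c(4, 1, 6, 3, 2, 5)
  fitP <- fitLTPub(PrevalenceTable("BMI", tb@values[perm],
                                   tb@prevalence[perm],
                                   referenceMean = 26.5))$model
  fit0 <- fitLTPub(tb)$model
  expect_equal(coef(fitP), coef(fit0), tolerance = 1e-12)
  expect_equal(affineTerm(fitP), affineTerm(fit0), tolerance = 1e-12)
  # shift covariate and reference mean together: same model
  fitS <- fitLTPub(PrevalenceTable("BMI", tb@values + 100, tb@prevalence,
                                   referenceMean = 126.5))$model
  expect_equal(coef(fitS), coef(fit0), tolerance = 1e-10)
  expect_equal(affineTerm(fitS), affineTerm(fit0), tolerance = 1e-10)
})

test_that("joint multi-covariate fit recovers both slopes and shared intercept", {
  m <- LiabilityModel(c(BMI = 0.08, age = 0.029), c(26.5, 50), -1.38)
  bmiVals <- c(20, 25, 30, 35)
  ageVals <- c(40, 50, 60, 70)
  Kbmi <- vapply(bmiVals, function(b) predictPrevalence(m, c(b, 50)), 0)
  Kage <- vapply(ageVals, function(a) predictPrevalence(m, c(26.5, a)), 0)
  fit <- fitLTPub(list(
    PrevalenceTable("BMI", bmiVals, Kbmi, referenceMean = 26.5),
    PrevalenceTable("age", ageVals, Kage, referenceMean = 50)))$model
  expect_equal(coef(fit), c(BMI = 0.08, age = 0.029), tolerance = 1e-8)
  expect_equal(affineTerm(fit), -1.38, tolerance = 1e-8)
})

test_that("weighted fit also recovers noiseless model-consistent data", {
  m <- LiabilityModel(c(x = 0.05), 50, -2.5)
  tv <- c(55, 65, 75, 85)
  K <- predictPrevalence(m, cbind(tv))
  fit <- fitLTPub(PrevalenceTable("x", tv, K, referenceMean = 50),
                  weighted = TRUE)$model
  expect_equal(coef(fit)[["x"]], 0.05, tolerance = 1e-8)
  expect_equal(affineTerm(fit), -2.5, tolerance = 1e-8)
})

test_that("invalid prevalence inputs are rejected", {
  expect_error(PrevalenceTable("x", c(1, 2), c(0, 0.5)), "strictly")
  expect_error(PrevalenceTable("x", c(1, 1), c(0.1, 0.2)), "distinct")
  expect_error(fitLTPub(list()), "PrevalenceTable")
})

test_that("covariate correlation diagnostics flag dependent pairs", {
  set.seed(21)
  x <- rnorm(1e4)
  co <- LTCohort(paste0("s", 1:1e4), rbinom(1e4, 1, 0.5),
                 cbind(a = x, b = x, c = -x, d = rnorm(1e4)))
  chk <- covariateCorrelationCheck(co)
  ab <- chk[chk$covariate1 == "a" & chk$covariate2 == "b", ]
  expect_equal(ab$r2, 1)
  expect_true(ab$flagged)
  ac <- chk[chk$covariate1 == "a" & chk$covariate2 == "c", ]
  expect_equal(ac$r2, 1)          # sign-invariant
  expect_true(ac$flagged)
  ad <- chk[chk$covariate1 == "a" & chk$covariate2 == "d", ]
  expect_lt(ad$r2, 0.01)
  expect_false(ad$flagged)
  expect_error(covariateCorrelationCheck(
    LTCohort("s1", 1L, cbind(a = 1))), "two covariates")
})
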