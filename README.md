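# ltassoc

Informed conditioning on clinical covariates for case-control genetic
association studies, built on the liability threshold (LT) model.

## The problem

Case-control GWAS cohorts are rarely random samples: individuals are
ascertained on disease status, and often on clinical covariates too
(BMI-matched, age-matched, or low-BMI-enriched designs). Covariates
such as BMI, age or smoking then carry information about how much
*genetic* risk each sample is likely to carry — a low-BMI type 2
diabetes case needed more genetic liability to cross the disease
threshold than a high-BMI case. Logistic regression cannot use this
information (in a matched design the covariate coefficient is forced to
zero), and conditioning on covariates in ascertained data can even lose
power.

`ltassoc` is for statistical geneticists and epidemiologists who want
to recover that power. It implements a three-step informed-conditioning
procedure:

1. **Fit the LT model from published prevalence data** (`fitLTPub`).
   The liability is $\phi = \sum_j c_j (t_j - \bar t_j) + m +
   \epsilon$ with $\epsilon \sim \mathcal{N}(0,1)$ under the null; an
   individual is a case iff $\phi \ge 0$. Since the model-implied
   prevalence is $K(t) = \Phi(\sum_j c_j (t_j - \bar t_j) + m)$, the
   probit transform of published prevalence-versus-covariate curves is
   linear in the covariates and $(c, m)$ drop out of a closed-form
   least-squares solve.
2. **Compute each sample's posterior mean residual liability**
   (`posteriorMeans`): truncated-normal tail expectations
   $\hat\epsilon = \phi(\tau)/\bar\Phi(\tau)$ for cases and
   $-\phi(\tau)/\Phi(\tau)$ for controls, where
   $\tau(t)$ is the sample-specific liability threshold; covariates
   measured at disease onset pin cases exactly at $\hat\epsilon = \tau$.
3. **Test association** (`ltTest`): a generalized Armitage trend test
   $\chi^2(1) = N\,r^2(g, \hat\epsilon)$ of allele dosage against the
   posterior means — a score test, with EIGENSTRAT-style
   residualization on principal components, liability-scale effect
   sizes, odds-ratio conversion and inverse-variance meta-analysis
   helpers.

The package also ships the standard comparison statistics (logistic
regression with/without covariates, 2-dof joint gene + gene×covariate
test, 1-dof interaction test, subset and case-only tests, optional
IPW), a vectorized simulation engine for stratified case-control
designs under liability or logit generative models, and closed-form
noncentral chi-square power calculations.

## Worked example

Fit the type 2 diabetes model from published prevalence-versus-BMI
values, compute posterior means, and test a simulated causal SNP:

```r
library(ltassoc)

bmi <- PrevalenceTable("BMI", c(18, 21.5, 24.5, 27.5, 30.5, 35),
                       c(0.02, 0.03, 0.05, 0.08, 0.13, 0.24),
                       referenceMean = 26.5)
model <- fitLTPub(bmi)$model
model
#> LiabilityModel
#>   phi = +0.08058*(BMI-26.5) -1.443 + eps
#>   prevalence at covariate means: 0.07456
```

The fitted coefficients round to the published 0.08 and −1.44: type 2
diabetes prevalence rises steeply with BMI, and BMI explains ~15% of
liability variance at a study BMI standard deviation of 5.25
(`varianceExplained(model, 5.25)`).

```r
co <- LTCohort(paste0("s", 1:4), c(1, 1, 0, 0),
               cbind(BMI = c(24, 35, 24, 35)))
round(posteriorMean(posteriorMeans(model, co)), 3)
#>     s1     s2     s3     s4
#>  2.062  1.335 -0.109 -0.386
```

The low-BMI case (s1) gets the most extreme pseudo-phenotype — it
needed the most genetic help — and the high-BMI control (s4) the most
negative. Testing one simulated causal SNP in the matched design (3,000
cases, 3,000 BMI-matched controls, per-allele liability effect 0.1,
allele frequency 0.5):

```r
sim <- simulateDataset(toyT2DDesign(gamma = 0.1), seed = 2026)
pm  <- posteriorMeans(model, sim$cohort)
ltTest(pm, sim$genotypes, model = model)
#>   snp_id    n    af statistic         p effect_liability      se    or
#> 1 causal 6000 0.517     55.53 9.223e-14           0.1375 0.01837 1.324

logrTest(caseStatus(sim$cohort), dosages(sim$genotypes)[, 1])$statistic
#> 49.24
```

On this dataset the LT statistic (55.5) clearly beats logistic
regression (49.2). Averaged over replicates the gap matches the
published simulation study:

```r
replicateStats(runReplicates(toyT2DDesign(gamma = 0.1),
                             tests = c("lt", "logr"),
                             nReplicates = 20000, seed = 9))
#>   test meanChisq    mcse nReplicates
#> 1   lt     30.16 0.07676       20000
#> 2 logr     28.01 0.07447       20000
```

against published averages of 30.34 (LT) and 27.88 (LogR).

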