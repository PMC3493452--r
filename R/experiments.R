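# Desk-scale reproductions of the simulation study: average chi-square
# table, genome-wide power curve, and null calibration for the matched
# BMI design.

.table2Gammas <- c(0, 0.06, 0.07, 0.08, 0.09, 0.1, 0.11, 0.12, 0.13,
                   0.14, 0.15)

#' Average chi-square statistics across effect sizes (matched BMI design)
#'
#' For each effect size, runs the replicate engine on the matched design
#' (\code{\link{toyT2DDesign}}) and tabulates the mean 1-dof chi-square of
#' each statistic with its Monte Carlo standard error.
#'
#' @param gammas effect-size grid.
#' @param tests statistics to include (engine test names).
#' @param reps replicates per effect size.
#' @param seed RNG seed; each effect size uses a distinct stream derived
#'   from it.
#' @return data.frame with columns \code{gamma}, \code{test},
#'   \code{meanChisq}, \code{mcse}, \code{nReplicates}.
#' @export
reproduceChisqTable <- function(gammas = .table2Gammas,
                                tests = c("logr", "logr_cov", "g_gxe",
                                          "logr_sub", "lt"),
                                reps = 1e5, seed = 1L) {
  out <- lapply(seq_along(gammas), function(i) {
    d <- toyT2DDesign(gamma = gammas[i])
    s <- runReplicates(d, tests = tests, alphas = 0.05,
                       nReplicates = reps, seed = seed + i - 1L)
    cbind(gamma = gammas[i], replicateStats(s))
  })
  do.call(rbind, out)
}

#' Genome-wide power curve and LT/LogR power ratio
#'
#' Power to reach \code{alpha} per statistic per effect size, with the
#' percent increase of the LT statistic's power over logistic regression
#' at each effect size and averaged over the grid.
#'
#' @param gammas effect-size grid (the default spans the chi-square table;
#'   gamma = 0 is excluded from ratio averaging since both powers vanish).
#' @param reps replicates per effect size (>= 1e5 recommended for tail
#'   stability at genome-wide alpha).
#' @param alpha significance threshold.
#' @param tests engine tests; must include \code{"lt"} and \code{"logr"}
#'   for the ratio.
#' @param seed RNG seed.
#' @return list with \code{power} (data.frame gamma x test) and
#'   \code{ratio} (data.frame with percent LT/LogR increase per gamma and
#'   row \code{gamma = NA} for the grid average).
#' @export
reproducePowerCurve <- function(gammas = .table2Gammas[-1L], reps = 1e5,
                                alpha = 5e-8,
                                tests = c("lt", "logr", "g_gxe"),
                                seed = 1L) {
  rows <- lapply(seq_along(gammas), function(i) {
    d <- toyT2DDesign(gamma = gammas[i])
    s <- runReplicates(d, tests = tests, alphas = alpha,
                       nReplicates = reps, seed = seed + i - 1L)
    cbind(gamma = gammas[i], replicatePower(s))
  })
  pw <- do.call(rbind, rows)
  ratio <- NULL
  if (all(c("lt", "logr") %in% tests)) {
    lt <- pw$power[pw$test == "lt"]
    lr <- pw$power[pw$test == "logr"]
    pct <- 100 * (lt / lr - 1)
    ratio <- data.frame(gamma = c(gammas, NA),
                        percentIncrease = c(pct, 100 * (mean(lt / lr) - 1)))
  }
  list(power = pw, ratio = ratio)
}

#' Null calibration of the LT statistic
#'
#' Distributional check of the LT statistic under the null (gamma = 0) in
#' the matched BMI design: mean chi-square, median-based genomic-control
#' lambda, tail fractions, and a Kolmogorov-Smirnov comparison with the
#' 1-dof chi-square distribution.
#'
#' @param reps replicate count.
#' @param seed RNG seed.
#' @param tails p-value thresholds to tabulate.
#' @return list with \code{meanChisq}, \code{mcse}, \code{lambda},
#'   \code{tailFractions} (named, observed fraction below each
#'   threshold), \code{ksP}, \code{nReplicates}.
#' @export
reproduceNullCalibration <- function(reps = 1e5, seed = 1L,
                                     tails = c(0.05, 0.01, 1e-4)) {
  d <- toyT2DDesign(gamma = 0)
  s <- runReplicates(d, tests = "lt", alphas = tails, nReplicates = reps,
                     seed = seed, keepStatistics = TRUE)
  stat <- replicateStatistics(s)[, "lt"]
  pw <- replicatePower(s)
  list(meanChisq = mean(stat),
       mcse = stats::sd(stat) / sqrt(length(stat)),
       lambda = stats::median(stat) / qchisq(0.5, 1L),
       tailFractions = setNames(pw$power, paste0("p<", pw$alpha)),
       ksP = suppressWarnings(ks.test(stat, stats::pchisq, df = 1)$p.value),
       nReplicates = reps)
}
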