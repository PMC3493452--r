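#' Simulation design for case-control power studies
#'
#' Describes one generative scenario: the liability model, the causal
#' SNP's per-allele effect \code{gamma} and population allele frequency
#' \code{maf}, an optional gene x covariate interaction on the liability
#' scale (\eqn{\epsilon = \gamma g_c + \delta\, g_c (t - \bar t) + N(0,1)}
#' with \eqn{g_c = g - 2\,\mathrm{maf}}), the generative family
#' (\code{"liability"} or \code{"logit"}), and the ascertainment scheme.
#'
#' For \code{case_control_covariate} ascertainment, \code{strata} gives
#' one row per (status, covariate) cell with a \code{count}; genotypes are
#' drawn from the exact conditional distribution \eqn{P(g \mid z, t)}. For
#' \code{random} ascertainment, \code{strata} gives covariate values and
#' counts (status is drawn by the model). For \code{case_control},
#' covariates are drawn from \code{strata} proportions and individuals are
#' forward-simulated with rejection until \code{nCases} and
#' \code{nControls} are reached.
#'
#' @slot model the analysis/generative \linkS4class{LiabilityModel}.
#' @slot gamma per-allele liability effect of the causal SNP.
#' @slot maf population counted-allele frequency.
#' @slot interaction liability units per (allele x covariate unit), on the
#'   first covariate; 0 for additive models.
#' @slot generator \code{"liability"} or \code{"logit"}.
#' @slot logitParams for the logit generator: list with \code{intercept},
#'   \code{genotype} (per-allele log odds) and \code{covariates} (named
#'   per-covariate log odds).
#' @slot ascertainment \code{"random"}, \code{"case_control"} or
#'   \code{"case_control_covariate"}.
#' @slot strata data.frame: \code{status} (0/1, ignored for random), one
#'   column per covariate, \code{count} (for case_control: proportions of
#'   the covariate distribution).
#' @slot nCases,nControls target counts for case_control ascertainment.
#' @slot nReplicates default replicate count for \code{\link{runReplicates}}.
#' @slot seed default RNG seed.
#' @slot genotypeCentering how the per-allele effect enters the liability:
#'   \code{"raw"} (default) applies \code{gamma} to the raw allele count,
#'   the convention that reproduces the published simulation averages;
#'   \code{"population"} applies it to the genotype centered at its
#'   population mean \code{2*maf} (the two differ only by an affine shift
#'   \code{2*gamma*maf} of the generative prevalence).
#' @slot unitTotalVariance if \code{TRUE} (default) the residual noise is
#'   scaled so the total liability variance given the covariates is 1
#'   (the classical threshold-model standardization,
#'   \eqn{\epsilon = \gamma g + N(0, 1 - \gamma^2 Var(g))}); if
#'   \code{FALSE} the noise is standard normal and the total variance is
#'   \eqn{1 + \gamma^2 Var(g)}.
#' @export
setClass("SimDesign",
  representation(model = "LiabilityModel", gamma = "numeric", maf = "numeric",
                 interaction = "numeric", generator = "character",
                 logitParams = "list", ascertainment = "character",
                 strata = "data.frame", nCases = "integer",
                 nControls = "integer", nReplicates = "integer",
                 seed = "integer", genotypeCentering = "character",
                 unitTotalVariance = "logical"))

setValidity("SimDesign", function(object) {
  if (!(object@generator %in% c("liability", "logit")))
    return("generator must be 'liability' or 'logit'")
  if (!(object@ascertainment %in%
        c("random", "case_control", "case_control_covariate")))
    return("unknown ascertainment scheme")
  if (object@maf <= 0 || object@maf >= 1) return("maf must be in (0, 1)")
  if (!is.finite(object@gamma) || !is.finite(object@interaction))
    return("gamma and interaction must be finite")
  st <- object@strata
  if (!nrow(st) || !("count" %in% names(st)))
    return("strata must have rows and a 'count' column")
  if (any(st$count <= 0)) return("stratum counts must be positive")
  if (object@ascertainment == "case_control_covariate") {
    if (!("status" %in% names(st)) || !all(st$status %in% c(0, 1)))
      return("case_control_covariate strata need a 0/1 status column")
  }
  if (object@ascertainment == "case_control" &&
      (object@nCases < 1L || object@nControls < 1L))
    return("case_control ascertainment needs positive nCases and nControls")
  if (!(object@genotypeCentering %in% c("raw", "population")))
    return("genotypeCentering must be 'raw' or 'population'")
  if (length(object@unitTotalVariance) != 1L ||
      is.na(object@unitTotalVariance))
    return("unitTotalVariance must be TRUE or FALSE")
  if (object@generator == "logit") {
    lp <- object@logitParams
    if (!all(c("intercept", "genotype") %in% names(lp)))
      return("logit generator needs logitParams$intercept and $genotype")
  }
  TRUE
})

#' @describeIn SimDesign-class constructor.
#' @param model,gamma,maf,interaction,generator,logitParams,ascertainment,strata,nCases,nControls,nReplicates,seed,genotypeCentering,unitTotalVariance
#'   see the corresponding slots.
#' @export
SimDesign <- function(model, gamma = 0, maf = 0.5, interaction = 0,
                      generator = c("liability", "logit"),
                      logitParams = list(),
                      ascertainment = c("case_control_covariate", "random",
                                        "case_control"),
                      strata, nCases = 0L, nControls = 0L,
                      nReplicates = 1e5, seed = 1L,
                      genotypeCentering = c("raw", "population"),
                      unitTotalVariance = TRUE) {
  new("SimDesign", model = model, gamma = as.numeric(gamma),
      maf = as.numeric(maf), interaction = as.numeric(interaction),
      generator = match.arg(generator), logitParams = logitParams,
      ascertainment = match.arg(ascertainment),
      strata = as.data.frame(strata), nCases = as.integer(nCases),
      nControls = as.integer(nControls),
      nReplicates = as.integer(nReplicates), seed = as.integer(seed),
      genotypeCentering = match.arg(genotypeCentering),
      unitTotalVariance = isTRUE(unitTotalVariance))
}

setMethod("show", "SimDesign", function(object) {
  cat(sprintf("SimDesign: %s generator, %s ascertainment\n",
              object@generator, object@ascertainment))
  cat(sprintf("  gamma = %g, maf = %g, interaction = %g\n",
              object@gamma, object@maf, object@interaction))
  cat(sprintf("  %d strata, %d replicates by default\n",
              nrow(object@strata), object@nReplicates))
})

#' The matched BMI case-control-covariate study design
#'
#' The canonical stratified design used throughout the simulation study:
#' 3,000 cases and 3,000 BMI-matched controls, half of each at BMI 24 and
#' half at BMI 35, under the single-covariate type 2 diabetes liability
#' model (c = 0.08, reference mean 26.5, affine -1.44), causal SNP with
#' population allele frequency 0.5.
#'
#' @param gamma per-allele liability effect (0 for the null).
#' @param interaction gene x BMI interaction on the liability scale.
#' @param nPerStratum samples per (status, BMI) cell (default 1500).
#' @param nReplicates,seed engine defaults.
#' @return A \linkS4class{SimDesign}.
#' @export
toyT2DDesign <- function(gamma = 0.1, interaction = 0, nPerStratum = 1500L,
                         nReplicates = 1e5, seed = 1L) {
  model <- LiabilityModel(c(BMI = 0.08), 26.5, -1.44)
  strata <- data.frame(status = c(1L, 1L, 0L, 0L), BMI = c(24, 35, 24, 35),
                       count = rep(as.integer(nPerStratum), 4L))
  SimDesign(model, gamma = gamma, maf = 0.5, interaction = interaction,
            strata = strata, nReplicates = nReplicates, seed = seed)
}

# per-stratum case probability given genotype, under either generator;
# g is raw dosage 0:2, covariates enter via the design's model/logitParams
.caseProbGivenG <- function(design, tRow, g) {
  m <- design@model
  gc <- if (design@genotypeCentering == "population") g - 2 * design@maf else g
  gamEff <- design@gamma
  if (design@interaction != 0 && length(m@coefficients))
    gamEff <- gamEff + design@interaction * (tRow[[1L]] - m@referenceMeans[1L])
  if (design@generator == "liability") {
    tau <- liabilityThreshold(m, as.numeric(tRow))
    sdres <- 1
    if (design@unitTotalVariance) {
      vg <- 2 * design@maf * (1 - design@maf)
      v <- 1 - gamEff^2 * vg
      if (v <= 0)
        stop("genetic effect explains the entire liability variance")
      sdres <- sqrt(v)
    }
    pnorm((tau - gamEff * gc) / sdres, lower.tail = FALSE)
  } else {
    lp <- design@logitParams
    eta <- lp$intercept + lp$genotype * g
    if (length(lp$covariates))
      eta <- eta + sum(unlist(lp$covariates) * as.numeric(tRow))
    plogis(eta)
  }
}

# exact conditional genotype distribution P(g | z, t) for one stratum
.stratumProbs <- function(design, tRow, status) {
  maf <- design@maf
  hwe <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
  pcase <- .caseProbGivenG(design, tRow, 0:2)
  w <- hwe * if (status == 1) pcase else 1 - pcase
  s <- sum(w)
  if (s <= 0 || !is.finite(s)) stop("infeasible stratum: prevalence 0 or 1")
  w / s
}

.covariateColumns <- function(strata)
  setdiff(names(strata), c("status", "count"))

#' Simulate one dataset under the design
#'
#' Draws a cohort and the causal SNP's genotypes under the design's
#' generative model and ascertainment scheme. Stratified
#' (case-control-covariate) designs draw genotypes from the exact
#' conditional distribution \eqn{P(g \mid z, t)} (or, with
#' \code{hweApprox}, binomially at the stratum allele frequency); random
#' and case-control designs simulate individuals forward through the
#' generative model, the latter with rejection until the target case and
#' control counts are reached.
#'
#' @param design a \linkS4class{SimDesign}.
#' @param seed RNG seed (default: the design's).
#' @param hweApprox draw stratum genotypes as Binomial(2, stratum allele
#'   frequency) instead of the exact conditional distribution.
#' @return list with \code{cohort} (\linkS4class{LTCohort}) and
#'   \code{genotypes} (\linkS4class{GenotypeMatrix} with one SNP).
#' @export
simulateDataset <- function(design, seed = design@seed, hweApprox = FALSE) {
  set.seed(seed)
  st <- design@strata
  covCols <- .covariateColumns(st)
  asc <- design@ascertainment
  if (asc == "case_control_covariate") {
    gl <- vector("list", nrow(st))
    for (i in seq_len(nrow(st))) {
      p <- .stratumProbs(design, st[i, covCols, drop = FALSE], st$status[i])
      n <- st$count[i]
      gl[[i]] <- if (hweApprox) {
        af <- (p[2L] + 2 * p[3L]) / 2
        rbinom(n, 2L, af)
      } else sample(0:2, n, replace = TRUE, prob = p)
    }
    g <- unlist(gl)
    status <- rep(st$status, st$count)
    X <- st[rep(seq_len(nrow(st)), st$count), covCols, drop = FALSE]
  } else if (asc == "random") {
    n <- sum(st$count)
    X <- st[rep(seq_len(nrow(st)), st$count), covCols, drop = FALSE]
    g <- rbinom(n, 2L, design@maf)
    pcase <- vapply(seq_len(n), function(i)
      .caseProbGivenG(design, X[i, , drop = FALSE], g[i]), 0)
    status <- as.integer(runif(n) < pcase)
  } else {                                 # case_control, rejection
    need <- c(control = design@nControls, case = design@nCases)
    got <- list(); nCase <- 0L; nCtrl <- 0L
    budget <- 200L * (design@nCases + design@nControls)
    drawn <- 0L
    probs <- st$count / sum(st$count)
    while ((nCase < need["case"] || nCtrl < need["control"]) &&
           drawn < budget) {
      b <- 4L * (design@nCases + design@nControls)
      idx <- sample.int(nrow(st), b, replace = TRUE, prob = probs)
      Xb <- st[idx, covCols, drop = FALSE]
      gb <- rbinom(b, 2L, design@maf)
      pcase <- vapply(seq_len(b), function(i)
        .caseProbGivenG(design, Xb[i, , drop = FALSE], gb[i]), 0)
      zb <- as.integer(runif(b) < pcase)
      keep <- (zb == 1L & nCase + cumsum(zb == 1L) <= need["case"]) |
              (zb == 0L & nCtrl + cumsum(zb == 0L) <= need["control"])
      got[[length(got) + 1L]] <- data.frame(z = zb[keep], g = gb[keep],
                                            Xb[keep, , drop = FALSE])
      nCase <- nCase + sum(zb[keep] == 1L)
      nCtrl <- nCtrl + sum(zb[keep] == 0L)
      drawn <- drawn + b
    }
    if (nCase < need["case"] || nCtrl < need["control"])
      stop("rejection budget exceeded; is the disease prevalence degenerate?")
    all <- do.call(rbind, got)
    status <- all$z; g <- all$g
    X <- all[, covCols, drop = FALSE]
  }
  n <- length(status)
  ids <- paste0("s", seq_len(n))
  Xm <- as.matrix(X)
  rownames(Xm) <- NULL
  cohort <- LTCohort(ids, status,
                     if (length(covCols)) Xm else NULL)
  dos <- matrix(as.numeric(g), ncol = 1L,
                dimnames = list(ids, "causal"))
  list(cohort = cohort, genotypes = GenotypeMatrix(dos))
}

#' @rdname simulateDataset
#' @export
simulateLTDataset <- function(design, seed = design@seed, hweApprox = FALSE) {
  stopifnot(design@generator == "liability")
  simulateDataset(design, seed, hweApprox)
}

#' @rdname simulateDataset
#' @export
simulateLogitDataset <- function(design, seed = design@seed) {
  stopifnot(design@generator == "logit")
  simulateDataset(design, seed)
}
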