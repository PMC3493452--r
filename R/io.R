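# Delimited-text and VCF readers/writers. All text formats are
# tab-delimited by default; comma is accepted via `sep`.

.parsePrev <- function(x) {
  x <- trimws(as.character(x))
  pct <- grepl("%$", x)
  v <- as.numeric(sub("%$", "", x))
  v[pct] <- v[pct] / 100
  if (anyNA(v)) stop("non-numeric prevalence value")
  v
}

#' Read prevalence tables from delimited text
#'
#' Expected columns: \code{covariate} (or \code{covariate_name}),
#' \code{value}, \code{prevalence}. Prevalence is a proportion in (0, 1)
#' or a percentage with a trailing \code{"\%"}. One file may carry several
#' covariates; one \linkS4class{PrevalenceTable} per covariate is
#' returned. An optional \code{reference_mean} column (constant within
#' covariate) overrides the default data-mean reference.
#'
#' @param path input file.
#' @param sep field delimiter.
#' @return Named list of \linkS4class{PrevalenceTable} objects.
#' @export
readPrevalenceTables <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  names(df)[names(df) == "covariate_name"] <- "covariate"
  if (!all(c("covariate", "value", "prevalence") %in% names(df)))
    stop("prevalence file needs columns covariate, value, prevalence")
  out <- lapply(split(df, df$covariate), function(d)
    PrevalenceTable(d$covariate[1L], as.numeric(d$value),
                    .parsePrev(d$prevalence),
                    referenceMean = if ("reference_mean" %in% names(d))
                      as.numeric(d$reference_mean[1L]) else NA_real_))
  out[unique(df$covariate)]
}

#' Read a case-control cohort from delimited text
#'
#' Required columns \code{sample_id} and \code{status}; every other
#' column becomes a numeric covariate. Missing values are encoded
#' \code{"NA"}. Status is 0/1, or 1/2 (PLINK-style, 2 = case) with
#' \code{statusCoding = "12"}.
#'
#' @param path input file.
#' @param sep field delimiter.
#' @param statusCoding \code{"01"} (default) or \code{"12"}.
#' @param onsetCovariates names of covariates measured at disease onset
#'   in cases.
#' @return An \linkS4class{LTCohort}. A warning is raised (parse still
#'   succeeds) when only one status class is present.
#' @export
readCohort <- function(path, sep = "\t", statusCoding = c("01", "12"),
                       onsetCovariates = character(0)) {
  statusCoding <- match.arg(statusCoding)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = "NA")
  if (!all(c("sample_id", "status") %in% names(df)))
    stop("cohort file needs columns sample_id and status")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids")
  status <- df$status
  if (statusCoding == "12") {
    if (!all(status %in% 1:2)) stop("expected 1/2 status coding")
    status <- status - 1L
  }
  if (!all(status %in% 0:1)) stop("status must be coded 0/1")
  covCols <- setdiff(names(df), c("sample_id", "status"))
  X <- NULL
  if (length(covCols)) {
    X <- as.matrix(df[covCols])
    if (!is.numeric(X)) stop("non-numeric covariate values")
  }
  if (length(unique(status)) < 2L)
    warning("only one status class present; association tests will fail")
  unknownOnset <- setdiff(onsetCovariates, covCols)
  if (length(unknownOnset))
    stop("onset covariate(s) not in file: ",
         paste(unknownOnset, collapse = ", "))
  LTCohort(df$sample_id, status, X,
           onsetFlags = if (length(covCols)) covCols %in% onsetCovariates)
}

#' @rdname readCohort
#' @param cohort an \linkS4class{LTCohort} to write.
#' @export
writeCohort <- function(cohort, path, sep = "\t") {
  df <- data.frame(sample_id = cohort@sampleIds, status = cohort@status)
  if (ncol(cohort@covariates)) df <- cbind(df, cohort@covariates)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

# dosage from VCF GT strings ("0/1", "1|1", "./."); ALT allele counted
.gtToDosage <- function(gt) {
  d <- rep(NA_real_, length(gt))
  d[gt %in% c("0/0", "0|0")] <- 0
  d[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1
  d[gt %in% c("1/1", "1|1")] <- 2
  d
}

#' Read genotypes from VCF or a delimited dosage matrix
#'
#' VCF: biallelic SNP records only; multi-allelic or non-SNP records are
#' skipped with a message and counted. The DS (dosage) FORMAT field is
#' preferred when present, otherwise GT is converted to ALT-allele counts.
#' Dosage matrix: delimited text, first column \code{sample_id}, one
#' column per SNP, missing as \code{"NA"}.
#'
#' @param path input file.
#' @param format \code{"auto"} (by extension), \code{"vcf"} or
#'   \code{"dosage"}.
#' @param sep delimiter for the dosage-matrix format.
#' @return A \linkS4class{GenotypeMatrix}; the number of skipped VCF
#'   records is available as \code{metadata(x)$skipped}.
#' @export
readGenotypes <- function(path, format = c("auto", "vcf", "dosage"),
                          sep = "\t") {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz|\\.bgz)?$", path)) "vcf" else "dosage"
  if (format == "vcf") {
    vcf <- VariantAnnotation::readVcf(path)
    ref <- as.character(VariantAnnotation::ref(vcf))
    altL <- VariantAnnotation::alt(vcf)
    nAlt <- S4Vectors::elementNROWS(altL)
    alt <- rep(NA_character_, length(nAlt))
    alt[nAlt == 1L] <- as.character(unlist(altL[nAlt == 1L]))
    isSnp <- nAlt == 1L & nchar(ref) == 1L & !is.na(alt) & nchar(alt) == 1L
    skipped <- sum(!isSnp)
    if (skipped)
      message(skipped, " multi-allelic or non-SNP record(s) skipped")
    vcf <- vcf[isSnp, ]
    gen <- VariantAnnotation::geno(vcf)
    if ("DS" %in% names(gen)) {
      D <- gen$DS
      storage.mode(D) <- "double"
    } else if ("GT" %in% names(gen)) {
      gt <- gen$GT
      D <- matrix(.gtToDosage(gt), nrow = nrow(gt),
                  dimnames = dimnames(gt))
    } else stop("VCF carries neither DS nor GT")
    rr <- SummarizedExperiment::rowRanges(vcf)
    info <- data.frame(
      snp_id = names(vcf),
      chr = as.character(GenomeInfoDb::seqnames(rr)),
      pos = BiocGenerics::start(rr),
      ref = ref[isSnp], alt = alt[isSnp])
    gm <- GenotypeMatrix(t(D), snpInfo = info)
    S4Vectors::metadata(gm)$skipped <- skipped
    gm
  } else {
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, na.strings = "NA",
                            check.names = FALSE)
    if (names(df)[1L] != "sample_id")
      stop("dosage matrix must start with a sample_id column")
    D <- as.matrix(df[-1L])
    rownames(D) <- df$sample_id
    GenotypeMatrix(D)
  }
}

#' @rdname readGenotypes
#' @param geno a \linkS4class{GenotypeMatrix} to write (dosage format).
#' @export
writeDosageMatrix <- function(geno, path, sep = "\t") {
  D <- dosages(geno)
  df <- data.frame(sample_id = rownames(D), check.names = FALSE)
  df <- cbind(df, as.data.frame(D, check.names = FALSE))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write association results as delimited text
#'
#' Fixed column order: snp_id, chr, pos, n, af, statistic, p,
#' effect_liability, se, or.
#'
#' @param res data.frame from \code{\link{ltTest}}.
#' @param path output file.
#' @param sep field delimiter.
#' @export
writeAssocResults <- function(res, path, sep = "\t") {
  cols <- c("snp_id", "chr", "pos", "n", "af", "statistic", "p",
            "effect_liability", "se", "or")
  extra <- setdiff(names(res), c(cols, "defined"))
  utils::write.table(res[, c(cols, extra)], path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Published epidemiological liability models bundled with the package
#'
#' Liability-scale models for seven diseases fitted from published
#' prevalence-versus-covariate curves (type 2 diabetes, prostate cancer,
#' lung cancer, breast cancer, rheumatoid arthritis, end-stage kidney
#' disease, age-related macular degeneration), with single- and
#' multi-covariate variants where available. Binary covariates (sex,
#' smoking status, the BMI > 30 indicator) are 0/1 numeric.
#'
#' @param disease optional disease identifier to filter on (e.g.
#'   \code{"T2D"}).
#' @return data.frame of the catalogue when \code{model = FALSE} (one row
#'   per model), otherwise a list of \linkS4class{LiabilityModel} objects
#'   named \code{disease:covariates}.
#' @param model return constructed models (default) or the raw catalogue.
#' @export
publishedModels <- function(disease = NULL, model = TRUE) {
  path <- system.file("extdata", "published_lt_models.tsv",
                      package = "ltassoc", mustWork = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!is.null(disease)) df <- df[df$disease %in% disease, , drop = FALSE]
  if (!model) return(df)
  out <- lapply(seq_len(nrow(df)), function(i) {
    nms <- strsplit(df$covariates[i], ",")[[1L]]
    LiabilityModel(
      coefficients = as.numeric(strsplit(df$coefficients[i], ",")[[1L]]),
      referenceMeans = as.numeric(strsplit(df$reference_means[i], ",")[[1L]]),
      affine = df$affine[i], covariateNames = nms)
  })
  names(out) <- paste0(df$disease, ":", df$covariates)
  out
}
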