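# shared fixtures, built in code

t2dModel <- function() LiabilityModel(c(BMI = 0.08), 26.5, -1.44)
prostateModel <- function() LiabilityModel(c(age = 0.05), 50, -2.5)

t2dPrevalenceTable <- function()
  PrevalenceTable("BMI", c(18, 21.5, 24.5, 27.5, 30.5, 35),
                  c(0.02, 0.03, 0.05, 0.08, 0.13, 0.24),
                  referenceMean = 26.5)

prostatePrevalenceTable <- function()
  PrevalenceTable("age", c(60, 70, 80), c(0.02, 0.08, 0.14),
                  referenceMean = 50)

# small cohort + genotypes with ids aligned
makeCohort <- function(n = 60, seed = 11, pCovariate = NULL) {
  set.seed(seed)
  ids <- sprintf("s%03d", seq_len(n))
  bmi <- round(rnorm(n, 27, 4), 1)
  status <- rbinom(n, 1, plogis((bmi - 27) / 6))
  LTCohort(ids, status, cbind(BMI = bmi))
}

makeGenotypes <- function(n = 60, nsnp = 3, seed = 12, maf = 0.4) {
  set.seed(seed)
  D <- matrix(rbinom(n * nsnp, 2, maf), n, nsnp,
              dimnames = list(sprintf("s%03d", seq_len(n)),
                              paste0("rs", seq_len(nsnp))))
  GenotypeMatrix(D)
}

writeVcfFixture <- function(path, withDS = FALSE) {
  hdr <- c("##fileformat=VCFv4.2",
           "##contig=<ID=1>",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  if (withDS)
    hdr <- c(hdr,
             '##FORMAT=<ID=DS,Number=1,Type=Float,Description="Dosage">')
  cols <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                  "INFO", "FORMAT", "sampA", "sampB"), collapse = "\t")
  fmt <- if (withDS) "GT:DS" else "GT"
  gv <- function(gt, ds) if (withDS) paste(gt, ds, sep = ":") else gt
  rows <- c(
    paste(c("1", "100", "rs1", "A", "G", ".", ".", ".", fmt,
            gv("0/1", "0.9"), gv("1/1", "1.8")), collapse = "\t"),
    paste(c("1", "200", "rs2", "C", "T", ".", ".", ".", fmt,
            gv("0/0", "0.1"), gv("0/1", "1.1")), collapse = "\t"),
    # multi-allelic record: must be skipped
    paste(c("1", "300", "rs3", "G", "A,T", ".", ".", ".", fmt,
            gv("0/1", "1.0"), gv("0/2", "1.0")), collapse = "\t"))
  writeLines(c(hdr, cols, rows), path)
  path
}
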