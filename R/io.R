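# Tab-separated IO for the pipeline's external formats. All files are
# UTF-8 TSV with "." for missing values.

fwriteTSV <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", na = ".", quote = FALSE)
}

freadTSV <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", na.strings = ".",
                                  data.table = FALSE))
}

#' Read / write an instrument table
#'
#' TSV with columns \code{snp, chrom, pos, effect_allele, other_allele,
#' beta, se, pval, eaf, annotation} (beta in years per effect allele;
#' se/pval optional).
#'
#' @param path file path.
#' @return an \code{InstrumentSet}.
#' @export
readInstruments <- function(path) {
  s <- freadTSV(path)
  if (is.null(s$annotation)) s$annotation <- "unknown"
  s$chrom <- as.character(s$chrom)
  new("InstrumentSet", snps = s)
}

#' @rdname readInstruments
#' @param instruments an \code{InstrumentSet}.
#' @export
writeInstruments <- function(instruments, path) {
  fwriteTSV(instruments@snps, path)
  invisible(path)
}

#' Read / write GWAS summary statistics
#'
#' TSV with columns \code{snp, effect_allele, other_allele, eaf, beta, se,
#' pval, n}.
#'
#' @param path file path.
#' @return data.frame.
#' @export
readSumstats <- function(path) freadTSV(path)

#' @rdname readSumstats
#' @param stats summary-statistics data.frame.
#' @export
writeSumstats <- function(stats, path) {
  fwriteTSV(stats, path)
  invisible(path)
}

#' Write a simulated cohort to a directory of TSV files
#'
#' Emits \code{genotypes.tsv} (individuals x SNPs, header = SNP ids),
#' \code{covariates.tsv}, \code{exposure.tsv} (when present),
#' \code{phenome.tsv} and \code{phenome_meta.tsv}.
#'
#' @param cohort a \code{CohortData}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fwriteTSV(as.data.frame(genotypes(cohort)), file.path(dir, "genotypes.tsv"))
  fwriteTSV(covariates(cohort), file.path(dir, "covariates.tsv"))
  if (!is.null(exposure(cohort)))
    fwriteTSV(data.frame(exposure = exposure(cohort)),
              file.path(dir, "exposure.tsv"))
  fwriteTSV(phenome(cohort), file.path(dir, "phenome.tsv"))
  fwriteTSV(phenomeMeta(cohort), file.path(dir, "phenome_meta.tsv"))
  invisible(dir)
}

#' Read a cohort written by \code{\link{writeCohort}}
#'
#' @param dir directory containing the cohort TSV files.
#' @return a \code{CohortData}.
#' @export
readCohort <- function(dir) {
  g <- as.matrix(freadTSV(file.path(dir, "genotypes.tsv")))
  expoPath <- file.path(dir, "exposure.tsv")
  new("CohortData", genotypes = g,
      covariates = freadTSV(file.path(dir, "covariates.tsv")),
      exposure = if (file.exists(expoPath)) freadTSV(expoPath)$exposure
                 else numeric(0),
      phenome = freadTSV(file.path(dir, "phenome.tsv")),
      phenomeMeta = {
        m <- freadTSV(file.path(dir, "phenome_meta.tsv"))
        m$ordered_levels[is.na(m$ordered_levels)] <- ""
        m
      })
}

#' Read a simulation configuration from a YAML file
#'
#' Keys mirror the arguments of \code{\link{simConfig}}; \code{traitSpec}
#' is a list of per-field mappings passed to \code{\link{traitSpec}}.
#'
#' @param path YAML file.
#' @return a \code{SimConfig}.
#' @export
readSimConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$traitSpec)) {
    y$traitSpec <- do.call(rbind, lapply(y$traitSpec, function(row)
      do.call(traitSpec, row)))
  }
  do.call(simConfig, y)
}
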