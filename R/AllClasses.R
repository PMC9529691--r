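#' Simulation configuration for synthetic MR-pheWAS cohorts
#'
#' An S4 container describing one synthetic study population: genotype
#' panel, exposure model, confounding, pleiotropy regime and the phenome
#' trait descriptors. Construct with \code{\link{simConfig}}.
#'
#' The exposure is parameterised on the scale of age at natural menopause
#' (ANM): a marginal mean of 50 years and standard deviation of 5 years,
#' with the instrument score explaining \code{targetR2} of its variance.
#'
#' @slot nIndividuals number of individuals.
#' @slot nSnps number of instrument SNPs.
#' @slot mafRange minor/effect allele frequency range, both in (0, 1).
#' @slot exposureMean,exposureSd marginal exposure moments (years).
#' @slot targetR2 fraction of exposure variance explained by the true
#'   genetic score, in [0, 1).
#' @slot confounderExposure,confounderOutcome per-SD slopes of the latent
#'   confounder on the exposure (years) and on every outcome's linear
#'   predictor.
#' @slot pleiotropyMode one of \code{"none"}, \code{"balanced"},
#'   \code{"directional"}: distribution of per-allele direct SNP-outcome
#'   effects (mean zero for balanced, \code{pleiotropyMean} for directional).
#' @slot pleiotropyMean,pleiotropySd direct-effect scale per oriented allele.
#' @slot traitSpec data.frame of phenome-field descriptors; see
#'   \code{\link{traitSpec}}.
#' @slot missingRate fraction of dosages set missing.
#' @slot ldBlockSize,ldBlockR optional block-correlation structure for
#'   genotypes (block size 1 means unlinked); used to exercise pruning.
#' @slot popStructure when TRUE, PC1 induces an allele-frequency gradient.
#' @slot seed integer seed; all randomness derives from it.
#'
#' @exportClass SimConfig
setClass("SimConfig",
  representation(
    nIndividuals = "integer",
    nSnps = "integer",
    mafRange = "numeric",
    exposureMean = "numeric",
    exposureSd = "numeric",
    targetR2 = "numeric",
    confounderExposure = "numeric",
    confounderOutcome = "numeric",
    pleiotropyMode = "character",
    pleiotropyMean = "numeric",
    pleiotropySd = "numeric",
    traitSpec = "data.frame",
    missingRate = "numeric",
    ldBlockSize = "integer",
    ldBlockR = "numeric",
    popStructure = "logical",
    seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nIndividuals < 1L) msg <- c(msg, "nIndividuals must be >= 1")
  if (object@nSnps < 1L) msg <- c(msg, "nSnps must be >= 1")
  if (length(object@mafRange) != 2L || any(object@mafRange <= 0) ||
      any(object@mafRange >= 1) || object@mafRange[1] > object@mafRange[2])
    msg <- c(msg, "mafRange must be an increasing pair in (0, 1)")
  if (object@exposureSd <= 0) msg <- c(msg, "exposureSd must be > 0")
  if (object@targetR2 < 0 || object@targetR2 >= 1)
    msg <- c(msg, "targetR2 must lie in [0, 1)")
  if (!object@pleiotropyMode %in% c("none", "balanced", "directional"))
    msg <- c(msg, "pleiotropyMode must be none/balanced/directional")
  if (nrow(object@traitSpec) == 0L)
    msg <- c(msg, "traitSpec must describe at least one phenome field")
  if (anyDuplicated(object@traitSpec$field_id))
    msg <- c(msg, "traitSpec field ids must be unique")
  if (!all(object@traitSpec$type %in%
           c("continuous", "binary", "ordered_categorical",
             "unordered_categorical")))
    msg <- c(msg, "traitSpec types must be continuous/binary/ordered_categorical/unordered_categorical")
  if (object@missingRate < 0 || object@missingRate >= 1)
    msg <- c(msg, "missingRate must lie in [0, 1)")
  # genetic + confounder variance cannot exceed the marginal variance
  if (object@confounderExposure^2 >
      (1 - object@targetR2) * object@exposureSd^2)
    msg <- c(msg, "confounderExposure^2 exceeds the residual exposure variance")
  if (length(msg)) msg else TRUE
})

#' Instrument SNP set for a genetic risk score
#'
#' Holds the per-SNP instrument table: identifiers, genomic position,
#' effect/other alleles, the published per-allele weight (years of ANM
#' change per effect allele, signed as published), effect-allele frequency
#' and DNA-damage-response (DDR) pathway annotation.
#'
#' @slot snps data.frame with columns \code{snp}, \code{chrom}, \code{pos},
#'   \code{effect_allele}, \code{other_allele}, \code{beta}, \code{eaf},
#'   \code{annotation} and optionally \code{se}, \code{pval}.
#' @exportClass InstrumentSet
setClass("InstrumentSet", representation(snps = "data.frame"))

setValidity("InstrumentSet", function(object) {
  s <- object@snps
  need <- c("snp", "chrom", "pos", "effect_allele", "other_allele",
            "beta", "eaf", "annotation")
  miss <- setdiff(need, colnames(s))
  if (length(miss))
    return(paste("missing instrument columns:", paste(miss, collapse = ", ")))
  msg <- character()
  if (anyDuplicated(s$snp)) msg <- c(msg, "SNP ids must be unique")
  if (any(s$effect_allele == s$other_allele))
    msg <- c(msg, "effect and other allele must differ")
  if (any(!is.na(s$pos) & s$pos < 1)) msg <- c(msg, "positions must be >= 1")
  if (any(!is.finite(s$beta) | s$beta == 0))
    msg <- c(msg, "weights must be finite and nonzero")
  if (any(s$eaf <= 0 | s$eaf >= 1))
    msg <- c(msg, "effect allele frequencies must lie in (0, 1)")
  if (!all(s$annotation %in% c("DDR", "non-DDR", "unknown")))
    msg <- c(msg, "annotation must be DDR/non-DDR/unknown")
  if (length(msg)) msg else TRUE
})

#' Per-individual weighted allele score
#'
#' A numeric vector of genetic risk scores (expected years of \emph{earlier}
#' menopause: the score counts ANM-decreasing alleles), with bookkeeping on
#' the number of SNPs used and the missing-dosage policy applied.
#'
#' @slot nSnpsUsed number of instrument SNPs contributing to the score.
#' @slot missingPolicy \code{"impute"} (oriented-frequency mean imputation)
#'   or \code{"complete"} (individuals with any missing dosage get NA).
#' @exportClass ScoreVector
setClass("ScoreVector", contains = "numeric",
         representation(nSnpsUsed = "integer", missingPolicy = "character"))

#' Individual-level synthetic cohort
#'
#' Genotype dosages, covariates (age, sex flag, 10 principal components),
#' the exposure (absent for male negative-control cohorts) and the phenome
#' table with its per-field metadata.
#'
#' @slot genotypes numeric matrix of dosages in [0, 2] (NA allowed),
#'   individuals in rows, SNPs in columns.
#' @slot covariates data.frame with \code{age}, \code{sex}, \code{PC1}..\code{PC10}.
#' @slot exposure numeric vector of exposure values (years), or length-0
#'   when the cohort has no exposure pathway (negative control).
#' @slot phenome data.frame of outcome columns.
#' @slot phenomeMeta data.frame with \code{field_id}, \code{declared_type},
#'   \code{ordered_levels} (pipe-separated, "" if none), \code{category}.
#' @exportClass CohortData
setClass("CohortData",
  representation(genotypes = "matrix", covariates = "data.frame",
                 exposure = "numeric", phenome = "data.frame",
                 phenomeMeta = "data.frame"))

setValidity("CohortData", function(object) {
  n <- nrow(object@genotypes)
  msg <- character()
  if (nrow(object@covariates) != n)
    msg <- c(msg, "covariate rows must match genotype rows")
  if (length(object@exposure) && length(object@exposure) != n)
    msg <- c(msg, "exposure length must match genotype rows (or be absent)")
  if (nrow(object@phenome) != n)
    msg <- c(msg, "phenome rows must match genotype rows")
  g <- object@genotypes
  if (any(g < 0 | g > 2, na.rm = TRUE))
    msg <- c(msg, "dosages must lie in [0, 2] or be missing")
  if (!all(c("field_id", "declared_type", "category") %in%
           colnames(object@phenomeMeta)))
    msg <- c(msg, "phenomeMeta needs field_id, declared_type, category")
  if (!all(object@phenomeMeta$declared_type %in%
           c("continuous", "binary", "ordered_categorical",
             "unordered_categorical", "auto")))
    msg <- c(msg, "declared types must be continuous/binary/ordered_categorical/unordered_categorical/auto")
  if (!all(object@phenomeMeta$field_id %in% colnames(object@phenome)))
    msg <- c(msg, "every phenomeMeta field must be a phenome column")
  if (length(msg)) msg else TRUE
})

#' A Mendelian randomization causal-effect estimate
#'
#' One causal estimate with its method label, standard error, 95\%
#' confidence interval and p-value. For MR-Egger the pleiotropy intercept
#' and its inference are carried alongside. The reporting sign convention
#' (\code{"decrease"}: per year decrease in the exposure; \code{"increase"})
#' is recorded in \code{sign}.
#'
#' @slot method method label, e.g. "IVW", "MR-Egger", "weighted median".
#' @slot estimate,se,ciLow,ciHigh,pvalue the estimate and its inference.
#' @slot intercept,interceptSE,interceptP Egger intercept terms (length 0
#'   for other methods).
#' @slot nSNPs,nObs numbers of instruments / individuals used.
#' @slot sign "decrease" or "increase".
#' @slot extra list of method-specific diagnostics (Cochran's Q, bootstrap
#'   settings, notes).
#' @exportClass MREstimate
setClass("MREstimate",
  representation(method = "character", estimate = "numeric", se = "numeric",
                 ciLow = "numeric", ciHigh = "numeric", pvalue = "numeric",
                 intercept = "numeric", interceptSE = "numeric",
                 interceptP = "numeric", nSNPs = "integer", nObs = "integer",
                 sign = "character", extra = "list"),
  prototype(intercept = numeric(0), interceptSE = numeric(0),
            interceptP = numeric(0), nSNPs = NA_integer_, nObs = NA_integer_,
            sign = "decrease", extra = list()))

setValidity("MREstimate", function(object) {
  msg <- character()
  if (is.finite(object@se) && object@se <= 0)
    msg <- c(msg, "se must be > 0")
  if (all(is.finite(c(object@ciLow, object@estimate, object@ciHigh))) &&
      !(object@ciLow <= object@estimate && object@estimate <= object@ciHigh))
    msg <- c(msg, "ciLow <= estimate <= ciHigh violated")
  if (is.finite(object@pvalue) && (object@pvalue < 0 || object@pvalue > 1))
    msg <- c(msg, "pvalue must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
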