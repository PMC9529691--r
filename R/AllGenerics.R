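#' @describeIn InstrumentSet-class number of instrument SNPs
#' @param x an object
#' @export
setGeneric("nInstruments", function(x) standardGeneric("nInstruments"))

#' @describeIn InstrumentSet-class SNP identifiers
#' @export
setGeneric("snpIds", function(x) standardGeneric("snpIds"))

#' @describeIn InstrumentSet-class per-allele weights (signed, as published)
#' @export
setGeneric("instrumentWeights", function(x) standardGeneric("instrumentWeights"))

#' @describeIn InstrumentSet-class DDR / non-DDR / unknown annotations
#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))

#' @describeIn CohortData-class genotype dosage matrix
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @describeIn CohortData-class covariate table (age, sex, PC1..PC10)
#' @export
setGeneric("covariates", function(x) standardGeneric("covariates"))

#' @describeIn CohortData-class exposure vector (NULL when absent)
#' @export
setGeneric("exposure", function(x) standardGeneric("exposure"))

#' @describeIn CohortData-class phenome outcome table
#' @export
setGeneric("phenome", function(x) standardGeneric("phenome"))

#' @describeIn CohortData-class per-field phenome metadata
#' @export
setGeneric("phenomeMeta", function(x) standardGeneric("phenomeMeta"))

setMethod("nInstruments", "InstrumentSet", function(x) nrow(x@snps))
setMethod("snpIds", "InstrumentSet", function(x) x@snps$snp)
setMethod("instrumentWeights", "InstrumentSet", function(x)
  setNames(x@snps$beta, x@snps$snp))
setMethod("annotations", "InstrumentSet", function(x)
  setNames(x@snps$annotation, x@snps$snp))

setMethod("genotypes", "CohortData", function(x) x@genotypes)
setMethod("covariates", "CohortData", function(x) x@covariates)
setMethod("exposure", "CohortData", function(x)
  if (length(x@exposure)) x@exposure else NULL)
setMethod("phenome", "CohortData", function(x) x@phenome)
setMethod("phenomeMeta", "CohortData", function(x) x@phenomeMeta)

#' @describeIn InstrumentSet-class coerce to data.frame
#' @param row.names,optional,... passed through (unused)
#' @export
setMethod("as.data.frame", "InstrumentSet",
          function(x, row.names = NULL, optional = FALSE, ...) x@snps)

#' @describeIn InstrumentSet-class subset instruments by index / id / logical
#' @param i index vector
#' @param j,drop unused
#' @export
setMethod("[", "InstrumentSet", function(x, i, j, ..., drop = FALSE) {
  s <- x@snps
  if (is.character(i)) i <- match(i, s$snp)
  new("InstrumentSet", snps = s[i, , drop = FALSE])
})

setMethod("show", "InstrumentSet", function(object) {
  s <- object@snps
  cat("InstrumentSet with", nrow(s), "SNPs",
      sprintf("(%d DDR, %d non-DDR, %d unknown)\n",
              sum(s$annotation == "DDR"), sum(s$annotation == "non-DDR"),
              sum(s$annotation == "unknown")))
  print(head(s, 5))
  if (nrow(s) > 5) cat("...", nrow(s) - 5, "more\n")
})

setMethod("show", "CohortData", function(object) {
  cat("CohortData:", nrow(object@genotypes), "individuals x",
      ncol(object@genotypes), "SNPs;",
      nrow(object@phenomeMeta), "phenome fields;",
      if (length(object@exposure)) "exposure present\n"
      else "no exposure (negative-control cohort)\n")
})

setMethod("show", "ScoreVector", function(object) {
  cat("ScoreVector over", length(object@.Data), "individuals,",
      object@nSnpsUsed, "SNPs, missing policy:", object@missingPolicy, "\n")
  print(summary(object@.Data))
})

setMethod("show", "MREstimate", function(object) {
  cat(sprintf("%s estimate (per year %s): %.4g (SE %.3g, 95%% CI %.4g to %.4g, p = %.3g)\n",
              object@method, object@sign, object@estimate, object@se,
              object@ciLow, object@ciHigh, object@pvalue))
  if (length(object@intercept))
    cat(sprintf("  intercept: %.4g (SE %.3g, p = %.3g)\n",
                object@intercept, object@interceptSE, object@interceptP))
  if (!is.null(object@extra$Q))
    cat(sprintf("  Cochran's Q: %.3g on %d df\n", object@extra$Q,
                object@extra$Qdf))
  if (!is.na(object@nSNPs)) cat("  instruments:", object@nSNPs, "\n")
  invisible(object)
})

#' Extract an MREstimate as a one-row data.frame
#'
#' @param x an \code{MREstimate}
#' @param row.names,optional,... unused
#' @return one-row data.frame with method, n_snps, estimate, se, ci_low,
#'   ci_high, pvalue, intercept terms and Cochran's Q where available.
#' @export
setMethod("as.data.frame", "MREstimate",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(method = x@method, n_snps = x@nSNPs,
               estimate = x@estimate, se = x@se,
               ci_low = x@ciLow, ci_high = x@ciHigh, pvalue = x@pvalue,
               intercept = if (length(x@intercept)) x@intercept else NA_real_,
               intercept_se = if (length(x@interceptSE)) x@interceptSE else NA_real_,
               intercept_p = if (length(x@interceptP)) x@interceptP else NA_real_,
               q_stat = x@extra$Q %||% NA_real_,
               sign = x@sign, stringsAsFactors = FALSE)
  })

# internal constructor with CI/p filled in from estimate and SE
makeMREstimate <- function(method, estimate, se, nSNPs = NA_integer_,
                           nObs = NA_integer_, sign = "decrease",
                           intercept = numeric(0), interceptSE = numeric(0),
                           extra = list()) {
  estimate <- unname(estimate); se <- unname(se)
  intercept <- unname(intercept); interceptSE <- unname(interceptSE)
  z <- 1.959963984540054
  pv <- 2 * pnorm(-abs(estimate / se))
  ip <- if (length(intercept)) 2 * pnorm(-abs(intercept / interceptSE))
        else numeric(0)
  new("MREstimate", method = method, estimate = estimate, se = se,
      ciLow = estimate - z * se, ciHigh = estimate + z * se, pvalue = pv,
      intercept = intercept, interceptSE = interceptSE, interceptP = ip,
      nSNPs = as.integer(nSNPs), nObs = as.integer(nObs), sign = sign,
      extra = extra)
}
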