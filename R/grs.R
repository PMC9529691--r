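#' Compute the weighted genetic risk score
#'
#' The score is a weighted sum of exposure-\emph{decreasing} allele counts:
#' each instrument is re-oriented so the counted allele decreases the
#' exposure (when the published weight for the effect allele is positive,
#' counting flips to the other allele, dosage \code{2 - d}, with the weight
#' magnitude), and the per-individual score is
#' \code{sum_j |w_j| * d*_ij} in units of expected years of earlier
#' menopause. Missing dosages are mean-imputed from the oriented allele
#' frequency (\code{2 * freq}) or, under \code{missingPolicy = "complete"},
#' propagate NA to that individual's score.
#'
#' @param genotypes numeric dosage matrix (individuals x SNPs, columns named
#'   by SNP id, values in [0, 2] or NA).
#' @param instruments an \code{InstrumentSet}.
#' @param missingPolicy \code{"impute"} (default) or \code{"complete"}.
#' @return a \code{ScoreVector}.
#' @examples
#' sim <- simulateCohort(simConfig(nIndividuals = 200, nSnps = 10, seed = 3))
#' grs <- computeGRS(genotypes(sim$cohort), sim$instruments)
#' @export
computeGRS <- function(genotypes, instruments,
                       missingPolicy = c("impute", "complete")) {
  missingPolicy <- match.arg(missingPolicy)
  stopifnot(is(instruments, "InstrumentSet"))
  s <- instruments@snps
  miss <- setdiff(s$snp, colnames(genotypes))
  if (length(miss))
    stop("instruments absent from genotype matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)
  g <- genotypes[, s$snp, drop = FALSE]
  if (any(g < 0 | g > 2, na.rm = TRUE))
    stop("dosages outside [0, 2]", call. = FALSE)
  flip <- s$beta > 0
  g[, flip] <- 2 - g[, flip]
  orientedFreq <- ifelse(flip, 1 - s$eaf, s$eaf)
  w <- abs(s$beta)
  if (anyNA(g)) {
    if (missingPolicy == "impute") {
      for (j in which(colSums(is.na(g)) > 0))
        g[is.na(g[, j]), j] <- 2 * orientedFreq[j]
    }
    # "complete": NAs propagate through the sum below
  }
  score <- drop(g %*% w)
  new("ScoreVector", score, nSnpsUsed = nrow(s),
      missingPolicy = missingPolicy)
}

#' Prune instruments by distance and dosage correlation
#'
#' Greedy selection in ascending published-GWAS p-value order (fallback:
#' descending \code{|beta|/se}, then ascending id). A candidate is dropped
#' when it lies within \code{windowBp} of an already-kept SNP on the same
#' chromosome, or when its squared dosage correlation with any kept SNP is
#' at least \code{r2Max}. Defaults follow the 10,000 kb / r-squared < 0.001
#' convention.
#'
#' @param instruments an \code{InstrumentSet} with positions.
#' @param genotypes dosage matrix used to estimate pairwise correlation.
#' @param windowBp exclusion window in base pairs (default 1e7 = 10,000 kb).
#' @param r2Max maximum allowed squared dosage correlation (default 0.001).
#' @return the pruned \code{InstrumentSet} (a subset, metadata preserved).
#' @export
pruneInstruments <- function(instruments, genotypes, windowBp = 1e7,
                             r2Max = 0.001) {
  stopifnot(is(instruments, "InstrumentSet"))
  s <- instruments@snps
  if (anyNA(s$pos) || anyNA(s$chrom))
    stop("instrument positions/chromosomes required for pruning",
         call. = FALSE)
  miss <- setdiff(s$snp, colnames(genotypes))
  if (length(miss))
    stop("instruments absent from genotype matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)
  ord <- if (!is.null(s$pval) && !anyNA(s$pval)) {
    order(s$pval, s$snp)
  } else if (!is.null(s$se) && !anyNA(s$se)) {
    order(-abs(s$beta) / s$se, s$snp)
  } else order(s$snp)
  g <- genotypes[, s$snp, drop = FALSE]
  kept <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (k in kept) {
      if (s$chrom[i] == s$chrom[k] &&
          abs(s$pos[i] - s$pos[k]) < windowBp) { ok <- FALSE; break }
      r <- suppressWarnings(cor(g[, i], g[, k],
                                use = "pairwise.complete.obs"))
      if (!is.na(r) && r^2 >= r2Max) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  new("InstrumentSet", snps = s[sort(kept), , drop = FALSE])
}

#' Stratify instruments by DNA-damage-response annotation
#'
#' @param instruments an \code{InstrumentSet} with annotations.
#' @param which \code{"DDR"} or \code{"non-DDR"}.
#' @return the matching subset (with a warning when empty); DDR and non-DDR
#'   subsets partition the annotated input.
#' @export
stratifyInstruments <- function(instruments, which = c("DDR", "non-DDR")) {
  which <- match.arg(which)
  stopifnot(is(instruments, "InstrumentSet"))
  s <- instruments@snps
  keep <- s$annotation == which
  if (!any(keep))
    warning("no instruments annotated ", which, call. = FALSE)
  new("InstrumentSet", snps = s[keep, , drop = FALSE])
}

#' Instrument-strength diagnostics
#'
#' Variance in the exposure explained by the score (R-squared from the
#' univariable regression of exposure on score) and the F-statistic. The
#' default is the single-regressor closed form
#' \code{F = R2 (n - 2) / (1 - R2)}; setting \code{nRegressors = k} gives
#' the k-regressor form \code{F = (R2 / k) ((n - k - 1) / (1 - R2))}.
#'
#' @param score a \code{ScoreVector} (or numeric vector).
#' @param exposure paired exposure values (years).
#' @param nRegressors regressor count for the F formula (default 1).
#' @return list with \code{r_squared}, \code{f_statistic} (+Inf when the
#'   fit is exact) and \code{n} (complete pairs).
#' @export
instrumentStrength <- function(score, exposure, nRegressors = 1L) {
  score <- as.numeric(score)
  ok <- complete.cases(score, exposure)
  n <- sum(ok)
  if (n < 3) stop("need at least 3 complete score/exposure pairs",
                  call. = FALSE)
  if (var(score[ok]) == 0)
    stop("degenerate instrument: score has zero variance", call. = FALSE)
  r2 <- cor(score[ok], exposure[ok])^2
  k <- nRegressors
  f <- if (r2 >= 1 - 1e-12) Inf
       else (r2 / k) * ((n - k - 1) / (1 - r2))
  list(r_squared = r2, f_statistic = f, n = n)
}
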