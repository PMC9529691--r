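ALLELE_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

#' Harmonize exposure and outcome GWAS summary statistics
#'
#' Matches SNPs by id and aligns the outcome associations to the exposure's
#' effect allele. Swapped allele labels flip the outcome beta's sign and
#' complement its frequency; strand-complement labels are resolved via the
#' A<->T / C<->G map. Palindromic (A/T, C/G) SNPs whose effect-allele
#' frequency lies in (0.42, 0.58) in either source are excluded (strand
#' unresolvable); palindromic SNPs outside that band are oriented by
#' frequency agreement. Irreconcilable allele pairs and unmatched SNPs are
#' excluded with a reason code.
#'
#' @param exposureStats,outcomeStats data.frames with columns \code{snp},
#'   \code{effect_allele}, \code{other_allele}, \code{eaf}, \code{beta},
#'   \code{se}.
#' @param ambiguousBand frequency band treated as strand-ambiguous for
#'   palindromic SNPs (default \code{c(0.42, 0.58)}).
#' @return list with \code{pairs} (data.frame \code{snp}, \code{eaf},
#'   \code{beta_x}, \code{se_x}, \code{beta_y}, \code{se_y}, effect alleles
#'   identical across the pair by construction) and \code{exclusions}
#'   (data.frame \code{snp}, \code{reason}).
#' @export
harmonizeSumstats <- function(exposureStats, outcomeStats,
                              ambiguousBand = c(0.42, 0.58)) {
  need <- c("snp", "effect_allele", "other_allele", "eaf", "beta", "se")
  for (nm in c("exposureStats", "outcomeStats")) {
    tab <- get(nm)
    miss <- setdiff(need, colnames(tab))
    if (length(miss))
      stop(nm, " is missing columns: ", paste(miss, collapse = ", "),
           call. = FALSE)
  }
  ex <- exposureStats; ou <- outcomeStats
  ex$effect_allele <- toupper(ex$effect_allele)
  ex$other_allele <- toupper(ex$other_allele)
  ou$effect_allele <- toupper(ou$effect_allele)
  ou$other_allele <- toupper(ou$other_allele)
  excl <- list()
  note <- function(snp, reason)
    excl[[length(excl) + 1L]] <<- data.frame(snp = snp, reason = reason,
                                             stringsAsFactors = FALSE)
  for (id in setdiff(ex$snp, ou$snp)) note(id, "unmatched_in_outcome")
  for (id in setdiff(ou$snp, ex$snp)) note(id, "unmatched_in_exposure")
  common <- intersect(ex$snp, ou$snp)
  rows <- list()
  for (id in common) {
    e <- ex[match(id, ex$snp), ]
    o <- ou[match(id, ou$snp), ]
    comp <- function(a) unname(ALLELE_COMPLEMENT[a])
    palindromic <- identical(comp(e$effect_allele), e$other_allele)
    flip <- NA
    if (palindromic) {
      inBand <- function(f) f > ambiguousBand[1] & f < ambiguousBand[2]
      if (inBand(e$eaf) || inBand(o$eaf)) {
        note(id, "palindromic_ambiguous")
        next
      }
      # orient by frequency agreement (labels cannot resolve strand)
      flip <- abs(e$eaf - o$eaf) > abs(e$eaf - (1 - o$eaf))
    } else if (o$effect_allele == e$effect_allele &&
               o$other_allele == e$other_allele) {
      flip <- FALSE
    } else if (o$effect_allele == e$other_allele &&
               o$other_allele == e$effect_allele) {
      flip <- TRUE
    } else if (identical(o$effect_allele, comp(e$effect_allele)) &&
               identical(o$other_allele, comp(e$other_allele))) {
      flip <- FALSE
    } else if (identical(o$effect_allele, comp(e$other_allele)) &&
               identical(o$other_allele, comp(e$effect_allele))) {
      flip <- TRUE
    } else {
      note(id, "allele_mismatch")
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      snp = id, eaf = e$eaf, beta_x = e$beta, se_x = e$se,
      beta_y = if (flip) -o$beta else o$beta, se_y = o$se,
      stringsAsFactors = FALSE)
  }
  pairs <- if (length(rows)) do.call(rbind, rows)
    else data.frame(snp = character(0), eaf = numeric(0),
                    beta_x = numeric(0), se_x = numeric(0),
                    beta_y = numeric(0), se_y = numeric(0))
  exclusions <- if (length(excl)) do.call(rbind, excl)
    else data.frame(snp = character(0), reason = character(0))
  rownames(pairs) <- rownames(exclusions) <- NULL
  list(pairs = pairs, exclusions = exclusions)
}

# shared input checks + reporting-sign reparameterization. Estimating on
# the per-year-DECREASE scale is the same problem with the exposure axis
# negated, so we flip beta_x once here and every estimator inherits the
# convention.
prepPairs <- function(pairs, sign, minPairs = 1L) {
  need <- c("beta_x", "se_x", "beta_y", "se_y")
  miss <- setdiff(need, colnames(pairs))
  if (length(miss))
    stop("pairs table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(pairs) < minPairs)
    stop("need at least ", minPairs, " SNP pair(s)", call. = FALSE)
  if (any(pairs$se_x <= 0 | pairs$se_y <= 0))
    stop("standard errors must be positive", call. = FALSE)
  if (sign == "decrease") pairs$beta_x <- -pairs$beta_x
  pairs
}

#' Wald ratio estimate from a single SNP
#'
#' \code{beta_Y / beta_X} with the first-order delta-method standard error
#' \code{se_Y / |beta_X|}.
#'
#' @param pairs one-row harmonized pair table.
#' @param sign "decrease" (default) or "increase" reporting convention.
#' @return an \code{MREstimate}.
#' @export
mrWaldRatio <- function(pairs, sign = c("decrease", "increase")) {
  sign <- match.arg(sign)
  pairs <- prepPairs(pairs[1, , drop = FALSE], sign)
  if (pairs$beta_x == 0)
    stop("Wald ratio undefined for beta_x = 0", call. = FALSE)
  makeMREstimate("Wald ratio", pairs$beta_y / pairs$beta_x,
                 pairs$se_y / abs(pairs$beta_x), nSNPs = 1L, sign = sign)
}

#' Inverse-variance-weighted (IVW) estimate
#'
#' Slope of the SNP-outcome on SNP-exposure associations through the
#' origin, weighted by \code{1 / se_Y^2}:
#' \code{sum(w bx by) / sum(w bx^2)}. The default standard error uses
#' multiplicative random effects -- the fixed-effect SE scaled by
#' \code{sqrt(max(1, Q / (k - 1)))} where Q is Cochran's heterogeneity
#' statistic -- with the fixed-effect SE available via
#' \code{randomEffects = FALSE}. A single pair delegates to
#' \code{\link{mrWaldRatio}}.
#'
#' @param pairs harmonized pair table (see \code{\link{harmonizeSumstats}}).
#' @param randomEffects scale the SE by residual heterogeneity (floored at
#'   1); default TRUE.
#' @inheritParams mrWaldRatio
#' @return an \code{MREstimate} with Cochran's Q in \code{extra}.
#' @export
mrIVW <- function(pairs, randomEffects = TRUE,
                  sign = c("decrease", "increase")) {
  sign <- match.arg(sign)
  if (nrow(pairs) == 1L) return(mrWaldRatio(pairs, sign))
  p <- prepPairs(pairs, sign, minPairs = 2L)
  w <- 1 / p$se_y^2
  denom <- sum(w * p$beta_x^2)
  est <- sum(w * p$beta_x * p$beta_y) / denom
  seF <- sqrt(1 / denom)
  k <- nrow(p)
  Q <- sum(w * (p$beta_y - est * p$beta_x)^2)
  phi <- Q / (k - 1)
  se <- if (randomEffects) seF * sqrt(max(1, phi)) else seF
  makeMREstimate("IVW", est, se, nSNPs = k, sign = sign,
                 extra = list(Q = Q, Qdf = k - 1L,
                              randomEffects = randomEffects))
}

#' MR-Egger regression
#'
#' Weighted regression of the SNP-outcome on SNP-exposure associations with
#' a free intercept (weights \code{1 / se_Y^2}), after orienting every pair
#' so the SNP-exposure association is non-negative. The slope estimates the
#' causal effect under the InSIDE assumption; a non-zero intercept
#' indicates unbalanced horizontal pleiotropy. SEs use the same
#' multiplicative random-effects scaling as \code{\link{mrIVW}} (floored at
#' 1).
#'
#' @inheritParams mrIVW
#' @return an \code{MREstimate} carrying the intercept, its SE and p-value.
#' @export
mrEgger <- function(pairs, randomEffects = TRUE,
                    sign = c("decrease", "increase")) {
  sign <- match.arg(sign)
  p <- prepPairs(pairs, sign, minPairs = 3L)
  flip <- p$beta_x < 0
  p$beta_x[flip] <- -p$beta_x[flip]
  p$beta_y[flip] <- -p$beta_y[flip]
  w <- 1 / p$se_y^2
  X <- cbind(intercept = 1, slope = p$beta_x)
  A <- crossprod(X, w * X)
  b <- solve(A, crossprod(X, w * p$beta_y))
  resid <- p$beta_y - drop(X %*% b)
  k <- nrow(p)
  Q <- sum(w * resid^2)
  phi <- Q / (k - 2)
  covF <- solve(A)
  scale <- if (randomEffects) sqrt(max(1, phi)) else 1
  se <- sqrt(diag(covF)) * scale
  makeMREstimate("MR-Egger", b["slope", 1], se["slope"], nSNPs = k,
                 sign = sign, intercept = b["intercept", 1],
                 interceptSE = unname(se["intercept"]),
                 extra = list(Q = Q, Qdf = k - 2L,
                              randomEffects = randomEffects))
}

# core of the weighted-median estimator: linear interpolation of the
# ratio at standardized cumulative weight 0.5
weightedMedianEstimate <- function(ratios, weights) {
  ord <- order(ratios)
  r <- ratios[ord]
  w <- weights[ord]
  cw <- (cumsum(w) - w / 2) / sum(w)
  if (0.5 <= cw[1]) return(r[1])
  k <- length(r)
  if (0.5 >= cw[k]) return(r[k])
  hit <- which(abs(cw - 0.5) < .Machine$double.eps^0.75)
  if (length(hit)) return(r[hit[1]])
  j <- max(which(cw < 0.5))
  r[j] + (r[j + 1] - r[j]) * (0.5 - cw[j]) / (cw[j + 1] - cw[j])
}

ratioTable <- function(p) {
  keep <- p$beta_x != 0
  if (!all(keep))
    message("excluding ", sum(!keep), " SNP(s) with beta_x = 0")
  p <- p[keep, , drop = FALSE]
  p$ratio <- p$beta_y / p$beta_x
  p$se_ratio <- p$se_y / abs(p$beta_x)
  p
}

#' Weighted median estimate
#'
#' Per-SNP Wald ratios ordered ascending with weights proportional to the
#' inverse ratio variance (delta method \code{se_Y / |beta_X|}); the
#' estimate interpolates the ratio at which the standardized cumulative
#' weight crosses one half. Consistent when valid instruments carry at
#' least 50\% of the weight. The SE comes from a seeded parametric
#' bootstrap resampling each \code{beta_X}, \code{beta_Y} from its SE.
#'
#' @inheritParams mrIVW
#' @param nBoot bootstrap replicates for the SE (default 1000).
#' @param seed bootstrap seed.
#' @return an \code{MREstimate}.
#' @export
mrWeightedMedian <- function(pairs, nBoot = 1000L, seed = 1L,
                             sign = c("decrease", "increase")) {
  sign <- match.arg(sign)
  p <- ratioTable(prepPairs(pairs, sign, minPairs = 3L))
  if (nrow(p) < 3L) stop("need at least 3 usable pairs", call. = FALSE)
  est <- weightedMedianEstimate(p$ratio, 1 / p$se_ratio^2)
  se <- bootstrapRatioSE(p, nBoot, seed, function(r, w)
    weightedMedianEstimate(r, w))
  makeMREstimate("weighted median", est, se, nSNPs = nrow(p), sign = sign,
                 extra = list(nBoot = nBoot, seed = seed))
}

# weighted kernel-density mode of the per-SNP ratios
modeEstimate <- function(ratios, weights, bandwidthFactor) {
  if (length(unique(ratios)) == 1L) return(ratios[1])
  k <- length(ratios)
  spread <- c(sd(ratios), mad(ratios))
  spread <- spread[spread > 0]
  h <- bandwidthFactor * 0.9 * min(spread) * k^(-1 / 5)
  d <- density(ratios, weights = weights / sum(weights), bw = h, n = 2048,
               from = min(ratios) - 3 * h, to = max(ratios) + 3 * h)
  d$x[which.max(d$y)]
}

#' Mode-based estimate (simple or weighted)
#'
#' Gaussian-kernel density over the per-SNP Wald ratios with bandwidth
#' \code{phi x} the modified-Silverman scale
#' \code{0.9 min(sd, mad) k^(-1/5)}; the estimate is the density argmax on
#' a fixed evaluation grid. The simple mode uses equal weights, the
#' weighted mode inverse-variance ratio weights. SE by seeded parametric
#' bootstrap.
#'
#' @inheritParams mrWeightedMedian
#' @param weighted use inverse-variance weights (TRUE) or equal weights.
#' @param bandwidthFactor bandwidth multiplier phi (default 1).
#' @return an \code{MREstimate}.
#' @export
mrMode <- function(pairs, weighted = FALSE, bandwidthFactor = 1,
                   nBoot = 1000L, seed = 1L,
                   sign = c("decrease", "increase")) {
  sign <- match.arg(sign)
  p <- ratioTable(prepPairs(pairs, sign, minPairs = 3L))
  if (nrow(p) < 3L) stop("need at least 3 usable pairs", call. = FALSE)
  wfun <- function(se_ratio) {
    if (weighted) 1 / se_ratio^2 else rep(1, length(se_ratio))
  }
  est <- modeEstimate(p$ratio, wfun(p$se_ratio), bandwidthFactor)
  se <- bootstrapRatioSE(p, nBoot, seed, function(r, w)
    modeEstimate(r, if (weighted) w else rep(1, length(r)),
                 bandwidthFactor))
  makeMREstimate(if (weighted) "weighted mode" else "simple mode",
                 est, se, nSNPs = nrow(p), sign = sign,
                 extra = list(nBoot = nBoot, seed = seed,
                              bandwidthFactor = bandwidthFactor))
}

# parametric bootstrap over (beta_x, beta_y) for ratio-based estimators;
# statistic receives re-derived ratios and inverse-variance weights
bootstrapRatioSE <- function(p, nBoot, seed, statistic) {
  withSubstream(seed, "ratio_boot", {
    k <- nrow(p)
    ests <- vapply(seq_len(nBoot), function(b) {
      bx <- rnorm(k, p$beta_x, p$se_x)
      by <- rnorm(k, p$beta_y, p$se_y)
      bx[bx == 0] <- .Machine$double.eps
      statistic(by / bx, (abs(bx) / p$se_y)^2)
    }, 0)
    sd(ests)
  })
}

#' Run the full two-sample estimator suite
#'
#' Convenience wrapper applying IVW, MR-Egger, weighted median and both
#' modes to one harmonized pair table.
#'
#' @inheritParams mrWeightedMedian
#' @param methods subset of c("ivw", "egger", "wmedian", "smode", "wmode").
#' @return data.frame with one row per method (columns as in
#'   \code{as.data.frame,MREstimate-method}).
#' @export
mrSuite <- function(pairs, methods = c("ivw", "egger", "wmedian", "smode",
                                       "wmode"),
                    nBoot = 1000L, seed = 1L,
                    sign = c("decrease", "increase")) {
  sign <- match.arg(sign)
  ests <- list(
    ivw = function() mrIVW(pairs, sign = sign),
    egger = function() mrEgger(pairs, sign = sign),
    wmedian = function() mrWeightedMedian(pairs, nBoot = nBoot,
                                          seed = seed, sign = sign),
    smode = function() mrMode(pairs, weighted = FALSE, nBoot = nBoot,
                              seed = seed, sign = sign),
    wmode = function() mrMode(pairs, weighted = TRUE, nBoot = nBoot,
                              seed = seed, sign = sign))
  do.call(rbind, lapply(methods, function(m) as.data.frame(ests[[m]]())))
}
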