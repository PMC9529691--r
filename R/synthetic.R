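#' Describe one phenome field for simulation
#'
#' Builds a one-row descriptor (or stack several with \code{rbind}) for
#' \code{\link{simConfig}}'s \code{traitSpec}.
#'
#' @param field_id unique field identifier.
#' @param type one of \code{"continuous"}, \code{"binary"},
#'   \code{"ordered_categorical"}, \code{"unordered_categorical"}.
#' @param effect true causal effect per year of exposure increase: mean
#'   difference (continuous / latent ordered scale), log-odds (binary), or
#'   the scale of category-specific multinomial slopes (unordered).
#' @param category free-text trait-category label (used in Fig-3-style
#'   summaries).
#' @param prevalence binary traits: target case fraction; the intercept is
#'   solved so the simulated prevalence matches.
#' @param n_levels ordered traits: number of levels (3..19).
#' @param n_categories unordered traits: number of categories.
#' @param noise_sd continuous traits: residual standard deviation.
#' @param pleiotropy per-trait override of the global pleiotropy mode
#'   (\code{NA} = inherit; else "none"/"balanced"/"directional").
#' @return data.frame with one row per field.
#' @export
traitSpec <- function(field_id, type, effect = 0, category = "general",
                      prevalence = 0.2, n_levels = 4L, n_categories = 3L,
                      noise_sd = 1, pleiotropy = NA_character_) {
  data.frame(field_id = as.character(field_id), type = type,
             effect = effect, category = category, prevalence = prevalence,
             n_levels = as.integer(n_levels),
             n_categories = as.integer(n_categories), noise_sd = noise_sd,
             pleiotropy = pleiotropy, stringsAsFactors = FALSE)
}

defaultTraitSpec <- function() {
  rbind(
    traitSpec("bmd_heel", "continuous", effect = 0.05, category = "bone"),
    traitSpec("alt_liver", "continuous", effect = 0, category = "liver"),
    traitSpec("hba1c", "continuous", effect = -0.02,
              category = "cardiometabolic"),
    traitSpec("breast_cancer", "binary", effect = 0.04,
              category = "cancer", prevalence = 0.1),
    traitSpec("t2d", "binary", effect = 0, category = "cardiometabolic",
              prevalence = 0.1),
    traitSpec("self_rated_health", "ordered_categorical", effect = 0.05,
              category = "general", n_levels = 4L),
    traitSpec("diet_group", "unordered_categorical", effect = 0,
              category = "lifestyle", n_categories = 3L),
    traitSpec("fvc", "continuous", effect = 0, category = "lung")
  )
}

#' Build a simulation configuration
#'
#' Defaults emulate the cohort structure the analysis assumes: an exposure
#' with marginal mean 50 years and SD 5 years (age at natural menopause),
#' instruments explaining 7.3\% of its variance, a latent confounder, and a
#' small mixed-type phenome. See \code{SimConfig} for slot meanings.
#'
#' @param nIndividuals,nSnps cohort and instrument panel size.
#' @param mafRange effect-allele frequency range.
#' @param exposureMean,exposureSd marginal exposure moments (years).
#' @param targetR2 variance in the exposure explained by the true score.
#' @param confounderExposure,confounderOutcome confounder slopes (per SD of
#'   the latent confounder, on the exposure in years and on every outcome
#'   linear predictor).
#' @param pleiotropyMode,pleiotropyMean,pleiotropySd global direct-effect
#'   regime and per-allele scale.
#' @param traitSpec phenome descriptors; see \code{\link{traitSpec}}.
#' @param missingRate fraction of dosages reported missing.
#' @param ldBlockSize,ldBlockR block-correlated genotypes (size 1 = unlinked).
#' @param popStructure add a PC1-driven allele-frequency gradient.
#' @param seed master integer seed.
#' @return a validated \code{SimConfig}.
#' @examples
#' cfg <- simConfig(nIndividuals = 500, nSnps = 20, seed = 7)
#' sim <- simulateCohort(cfg)
#' sim$cohort
#' @export
simConfig <- function(nIndividuals = 1000L, nSnps = 50L,
                      mafRange = c(0.05, 0.5), exposureMean = 50,
                      exposureSd = 5, targetR2 = 0.073,
                      confounderExposure = 1, confounderOutcome = 0.2,
                      pleiotropyMode = "none", pleiotropyMean = 0.01,
                      pleiotropySd = 0.005, traitSpec = defaultTraitSpec(),
                      missingRate = 0, ldBlockSize = 1L, ldBlockR = 0,
                      popStructure = FALSE, seed = 1L) {
  new("SimConfig", nIndividuals = as.integer(nIndividuals),
      nSnps = as.integer(nSnps), mafRange = as.numeric(mafRange),
      exposureMean = exposureMean, exposureSd = exposureSd,
      targetR2 = targetR2, confounderExposure = confounderExposure,
      confounderOutcome = confounderOutcome,
      pleiotropyMode = pleiotropyMode, pleiotropyMean = pleiotropyMean,
      pleiotropySd = pleiotropySd, traitSpec = traitSpec,
      missingRate = missingRate, ldBlockSize = as.integer(ldBlockSize),
      ldBlockR = ldBlockR, popStructure = popStructure,
      seed = as.integer(seed))
}

# -- internal draws ----------------------------------------------------------

# instrument panel: frequencies, signed per-allele weights, map positions.
# Weight magnitudes are scaled so the true score's variance equals
# targetR2 * exposureSd^2 under Hardy-Weinberg.
drawInstrumentPanel <- function(config) {
  withSubstream(config@seed, "panel", {
    m <- config@nSnps
    p <- runif(m, config@mafRange[1], config@mafRange[2])
    raw <- sample(c(-1, 1), m, replace = TRUE) * (0.3 + abs(rnorm(m)))
    varUnit <- sum(raw^2 * 2 * p * (1 - p))
    if (config@targetR2 > 0) {
      s <- sqrt(config@targetR2 * config@exposureSd^2 / varUnit)
      trueBeta <- raw * s
      pubBeta <- trueBeta
    } else {
      trueBeta <- rep(0, m)                    # no genetic path
      pubBeta <- raw * 0.05                    # published weights stay nonzero
    }
    if (config@ldBlockSize > 1L) {
      nblock <- ceiling(m / config@ldBlockSize)
      chrom <- rep(seq_len(nblock), each = config@ldBlockSize)[seq_len(m)]
      chrom <- ((chrom - 1L) %% 22L) + 1L
      offset <- stats::ave(seq_len(m), rep(seq_len(nblock),
                            each = config@ldBlockSize)[seq_len(m)],
                           FUN = seq_along)
      pos <- 1e6 + (offset - 1) * 1e6
    } else {
      chrom <- ((seq_len(m) - 1L) %% 22L) + 1L
      pos <- sort(sample(1e6:2.4e8, m, replace = FALSE))
    }
    # non-palindromic allele pairs so strand is always resolvable
    pairPool <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                     c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
    pick <- sample(seq_along(pairPool), m, replace = TRUE)
    ea <- vapply(pairPool[pick], `[`, "", 1L)
    oa <- vapply(pairPool[pick], `[`, "", 2L)
    ann <- ifelse(runif(m) < 104 / 267, "DDR", "non-DDR")
    pval <- 10^runif(m, -30, log10(5e-8))
    se <- abs(pubBeta) / qnorm(pval / 2, lower.tail = FALSE)
    snps <- data.frame(
      snp = sprintf("rs%06d", seq_len(m)), chrom = as.character(chrom),
      pos = as.numeric(pos), effect_allele = ea, other_allele = oa,
      beta = pubBeta, se = se, pval = pval, eaf = p, annotation = ann,
      stringsAsFactors = FALSE)
    list(instruments = new("InstrumentSet", snps = snps),
         trueBeta = setNames(trueBeta, snps$snp), maf = p)
  })
}

# Hardy-Weinberg genotypes; optional within-block latent-factor correlation
# and optional PC1-driven frequency gradient.
drawGenotypes <- function(config, panel, pc1, stream) {
  withSubstream(config@seed, stream, {
    n <- config@nIndividuals
    m <- config@nSnps
    p <- panel$maf
    g <- matrix(0, n, m, dimnames = list(NULL, names(panel$trueBeta)))
    if (config@ldBlockSize > 1L && config@ldBlockR > 0) {
      r <- config@ldBlockR
      block <- rep(seq_len(ceiling(m / config@ldBlockSize)),
                   each = config@ldBlockSize)[seq_len(m)]
      for (copy in 1:2) {
        f <- matrix(rnorm(n * max(block)), n)
        for (j in seq_len(m)) {
          z <- sqrt(r) * f[, block[j]] + sqrt(1 - r) * rnorm(n)
          g[, j] <- g[, j] + (pnorm(z) < p[j])
        }
      }
    } else {
      for (j in seq_len(m)) {
        pj <- if (config@popStructure)
          pmin(pmax(p[j] + 0.05 * pc1, 0.01), 0.99) else p[j]
        g[, j] <- rbinom(n, 1L, pj) + rbinom(n, 1L, pj)
      }
    }
    g
  })
}

drawCovariates <- function(config, sexFlag, stream) {
  withSubstream(config@seed, stream, {
    n <- config@nIndividuals
    cov <- data.frame(age = round(runif(n, 40, 69)),
                      sex = rep(sexFlag, n))
    for (k in pcCols()) cov[[k]] <- rnorm(n)
    cov
  })
}

# dosage of the exposure-DECREASING allele (2 - d when the published weight
# is positive, i.e. the effect allele increases the exposure)
orientDecreasing <- function(g, pubBeta) {
  flip <- pubBeta > 0
  g[, flip] <- 2 - g[, flip]
  g
}

# per-SNP direct (pleiotropic) outcome effects for one field; drawn from a
# field-keyed stream so both sexes share them under one seed. Effects act on
# the exposure-INCREASING oriented dosage so a directional mean creates a
# coherent score-outcome channel.
drawPleiotropy <- function(config, fieldId, mode) {
  if (mode == "none") return(NULL)
  withSubstream(config@seed, paste0("pleio_", fieldId), {
    mu <- if (mode == "directional") config@pleiotropyMean else 0
    rnorm(config@nSnps, mu, config@pleiotropySd)
  })
}

pleiotropyContribution <- function(g, pubBeta, alpha, maf) {
  if (is.null(alpha)) return(0)
  gInc <- g
  flip <- pubBeta < 0                      # orient to exposure-increasing
  gInc[, flip] <- 2 - gInc[, flip]
  pInc <- ifelse(flip, 1 - maf, maf)
  drop(scale(gInc, center = 2 * pInc, scale = FALSE) %*% alpha)
}

# generate one phenome field from its descriptor and linear predictor
generateField <- function(spec, lp, config, stream) {
  withSubstream(config@seed, stream, {
    n <- length(lp)
    switch(spec$type,
      continuous = lp + rnorm(n, 0, spec$noise_sd),
      binary = {
        a <- uniroot(function(a) mean(plogis(a + lp)) - spec$prevalence,
                     c(-40, 40))$root
        rbinom(n, 1L, plogis(a + lp))
      },
      ordered_categorical = {
        latent <- lp + rnorm(n)
        K <- spec$n_levels
        cuts <- quantile(latent, probs = seq_len(K - 1) / K)
        as.integer(cut(latent, c(-Inf, cuts, Inf), labels = FALSE))
      },
      unordered_categorical = {
        K <- spec$n_categories
        slope <- seq(-1, 1, length.out = K)
        eta <- outer(lp, slope)
        pr <- exp(eta - apply(eta, 1, max))
        pr <- pr / rowSums(pr)
        idx <- vapply(seq_len(n),
                      function(i) sample.int(K, 1L, prob = pr[i, ]), 1L)
        LETTERS[idx]
      },
      stop("unknown trait type: ", spec$type))
  })
}

buildPhenome <- function(config, exposureCentered, confounder, g, panel,
                         cohortTag) {
  ts <- config@traitSpec
  pheno <- vector("list", nrow(ts))
  alphaList <- vector("list", nrow(ts))
  names(pheno) <- names(alphaList) <- ts$field_id
  pubBeta <- panel$instruments@snps$beta
  for (k in seq_len(nrow(ts))) {
    spec <- ts[k, ]
    mode <- if (is.na(spec$pleiotropy)) config@pleiotropyMode
            else spec$pleiotropy
    alpha <- drawPleiotropy(config, spec$field_id, mode)
    alphaList[[k]] <- alpha
    lp <- spec$effect * exposureCentered +
      config@confounderOutcome * confounder +
      pleiotropyContribution(g, pubBeta, alpha, panel$maf)
    pheno[[k]] <- generateField(spec, lp,
                                config, paste0(cohortTag, "_", spec$field_id))
  }
  meta <- data.frame(
    field_id = ts$field_id,
    declared_type = ts$type,
    ordered_levels = ifelse(ts$type == "ordered_categorical",
      vapply(ts$n_levels, function(K) paste(seq_len(K), collapse = "|"), ""),
      ""),
    category = ts$category, stringsAsFactors = FALSE)
  list(phenome = as.data.frame(pheno, stringsAsFactors = FALSE,
                               optional = TRUE),
       meta = meta, alpha = alphaList)
}

injectMissing <- function(config, g, stream) {
  if (config@missingRate <= 0) return(g)
  withSubstream(config@seed, stream, {
    idx <- which(runif(length(g)) < config@missingRate)
    g[idx] <- NA_real_
    g
  })
}

#' Simulate an individual-level cohort with known ground truth
#'
#' Draws Hardy-Weinberg genotypes at the configured allele frequencies, an
#' exposure (age at natural menopause, years) driven by the instruments to
#' the configured variance explained plus a latent confounder, and a
#' mixed-type phenome causally downstream of the exposure, with optional
#' direct (pleiotropic) SNP-outcome effects. Deterministic under the
#' config's seed.
#'
#' @param config a \code{\link{simConfig}} object.
#' @return list with elements \code{cohort} (\code{CohortData}),
#'   \code{instruments} (\code{InstrumentSet}, weights as "published") and
#'   \code{truth} (per-SNP exposure effects, per-trait causal effects,
#'   per-SNP direct effects).
#' @seealso \code{\link{simulateMaleCohort}} for the negative-control
#'   population without the exposure pathway.
#' @export
simulateCohort <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  panel <- drawInstrumentPanel(config)
  cov <- drawCovariates(config, sexFlag = 0L, stream = "covariates_f")
  g <- drawGenotypes(config, panel, cov$PC1, stream = "genotypes_f")
  confounder <- withSubstream(config@seed, "confounder_f",
                              rnorm(config@nIndividuals))
  gc <- scale(g, center = 2 * panel$maf, scale = FALSE)
  genetic <- drop(gc %*% panel$trueBeta)
  noiseVar <- config@exposureSd^2 * (1 - config@targetR2) -
    config@confounderExposure^2
  expo <- withSubstream(config@seed, "exposure_f",
    config@exposureMean + genetic +
      config@confounderExposure * confounder +
      rnorm(config@nIndividuals, 0, sqrt(noiseVar)))
  ph <- buildPhenome(config, expo - config@exposureMean, confounder, g,
                     panel, "f")
  gOut <- injectMissing(config, g, "missing_f")
  cohort <- new("CohortData", genotypes = gOut, covariates = cov,
                exposure = expo, phenome = ph$phenome,
                phenomeMeta = ph$meta)
  truth <- list(snpEffects = panel$trueBeta,
                traitEffects = setNames(config@traitSpec$effect,
                                        config@traitSpec$field_id),
                pleiotropy = ph$alpha, config = config)
  class(truth) <- "truth_record"
  list(cohort = cohort, instruments = panel$instruments, truth = truth)
}

#' Simulate a male negative-control cohort
#'
#' Genotypes are drawn by the identical process (same instrument panel and
#' per-SNP direct effects under the same seed), but there is no exposure
#' variable and no exposure-mediated path into the phenome: fields receive
#' only confounder and (optional) pleiotropic SNP effects. A scan of the
#' score against this phenome isolates non-exposure-mediated channels.
#'
#' @inheritParams simulateCohort
#' @return list with \code{cohort} (\code{CohortData} without exposure) and
#'   \code{truth}.
#' @export
simulateMaleCohort <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  panel <- drawInstrumentPanel(config)
  cov <- drawCovariates(config, sexFlag = 1L, stream = "covariates_m")
  g <- drawGenotypes(config, panel, cov$PC1, stream = "genotypes_m")
  confounder <- withSubstream(config@seed, "confounder_m",
                              rnorm(config@nIndividuals))
  ph <- buildPhenome(config, rep(0, config@nIndividuals), confounder, g,
                     panel, "m")
  gOut <- injectMissing(config, g, "missing_m")
  cohort <- new("CohortData", genotypes = gOut, covariates = cov,
                exposure = numeric(0), phenome = ph$phenome,
                phenomeMeta = ph$meta)
  truth <- list(snpEffects = panel$trueBeta,
                traitEffects = setNames(rep(0, nrow(config@traitSpec)),
                                        config@traitSpec$field_id),
                pleiotropy = ph$alpha, config = config)
  class(truth) <- "truth_record"
  list(cohort = cohort, truth = truth)
}

#' Simulate paired GWAS summary statistics for two-sample MR
#'
#' Emits per-SNP exposure and outcome associations with standard errors
#' consistent with the stated GWAS sample sizes and allele frequencies.
#' Instruments are first oriented so the effect allele \emph{increases} the
#' exposure (all true SNP-exposure effects positive); per-SNP direct effects
#' \code{alpha} are drawn on that allele (zero under \code{"none"},
#' mean-zero under \code{"balanced"}, mean \code{pleiotropyMean} under
#' \code{"directional"}), so the MR-Egger intercept identifies the mean
#' direct effect under the InSIDE assumption.
#'
#' @param instruments an \code{InstrumentSet}.
#' @param trueEffect causal effect on the outcome per year \emph{increase}
#'   of the exposure.
#' @param pleiotropyMode "none", "balanced" or "directional".
#' @param pleiotropyMean,pleiotropySd direct-effect distribution.
#' @param nExposure,nOutcome GWAS sample sizes (>= 2).
#' @param sigmaExposure,sigmaOutcome residual SDs of the two GWAS traits
#'   (defaults: 5 years for the exposure, 1 for the outcome).
#' @param scrambleAlleles when TRUE, a random half of the outcome rows have
#'   their allele labels swapped (with beta and frequency flipped) so that
#'   \code{\link{harmonizeSumstats}} has real work to do.
#' @param seed integer seed.
#' @return list with \code{exposure} and \code{outcome} GWAS-format tables
#'   (snp, effect_allele, other_allele, eaf, beta, se, pval, n),
#'   \code{pairs} (harmonized \code{beta_x}/\code{se_x}/\code{beta_y}/
#'   \code{se_y} per SNP) and \code{truth}.
#' @export
simulateSummaryStats <- function(instruments, trueEffect,
                                 pleiotropyMode = "none",
                                 pleiotropyMean = 0.01, pleiotropySd = 0.005,
                                 nExposure = 200000, nOutcome = 100000,
                                 sigmaExposure = 5, sigmaOutcome = 1,
                                 scrambleAlleles = FALSE, seed = 1L) {
  stopifnot(is(instruments, "InstrumentSet"))
  if (nInstruments(instruments) == 0L) stop("empty instrument set")
  if (nExposure < 2 || nOutcome < 2) stop("GWAS sample sizes must be >= 2")
  if (!pleiotropyMode %in% c("none", "balanced", "directional"))
    stop("pleiotropyMode must be none/balanced/directional")
  s <- instruments@snps
  # orient to the exposure-increasing allele
  flip <- s$beta < 0
  tmp <- s$effect_allele[flip]
  s$effect_allele[flip] <- s$other_allele[flip]
  s$other_allele[flip] <- tmp
  s$eaf[flip] <- 1 - s$eaf[flip]
  bxTrue <- abs(s$beta)
  m <- nrow(s)
  withSubstream(seed, "sumstats", {
    alpha <- switch(pleiotropyMode,
      none = rep(0, m),
      balanced = rnorm(m, 0, pleiotropySd),
      directional = rnorm(m, pleiotropyMean, pleiotropySd))
    info <- 2 * s$eaf * (1 - s$eaf)
    seX <- sigmaExposure / sqrt(info * nExposure)
    seY <- sigmaOutcome / sqrt(info * nOutcome)
    bx <- bxTrue + rnorm(m, 0, seX)
    byTrue <- trueEffect * bxTrue + alpha
    by <- byTrue + rnorm(m, 0, seY)
    expoTab <- data.frame(snp = s$snp, effect_allele = s$effect_allele,
                          other_allele = s$other_allele, eaf = s$eaf,
                          beta = bx, se = seX,
                          pval = 2 * pnorm(-abs(bx / seX)), n = nExposure,
                          stringsAsFactors = FALSE)
    outTab <- data.frame(snp = s$snp, effect_allele = s$effect_allele,
                         other_allele = s$other_allele, eaf = s$eaf,
                         beta = by, se = seY,
                         pval = 2 * pnorm(-abs(by / seY)), n = nOutcome,
                         stringsAsFactors = FALSE)
    if (scrambleAlleles) {
      sw <- sample(c(TRUE, FALSE), m, replace = TRUE)
      tmp <- outTab$effect_allele[sw]
      outTab$effect_allele[sw] <- outTab$other_allele[sw]
      outTab$other_allele[sw] <- tmp
      outTab$beta[sw] <- -outTab$beta[sw]
      outTab$eaf[sw] <- 1 - outTab$eaf[sw]
    }
    pairs <- data.frame(snp = s$snp, eaf = s$eaf, beta_x = bx, se_x = seX,
                        beta_y = by, se_y = seY, stringsAsFactors = FALSE)
    list(exposure = expoTab, outcome = outTab, pairs = pairs,
         truth = list(trueEffect = trueEffect, alpha = alpha,
                      bxTrue = setNames(bxTrue, s$snp)))
  })
}
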