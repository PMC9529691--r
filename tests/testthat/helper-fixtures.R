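# Shared fixture builders: everything is generated in code at test time.

makeInstruments <- function(betas, eaf = NULL, chrom = NULL, pos = NULL,
                            annotation = NULL, pval = NULL,
                            ea = NULL, oa = NULL) {
  m <- length(betas)
  s <- data.frame(
    snp = sprintf("s%02d", seq_len(m)),
    chrom = if (is.null(chrom)) as.character(seq_len(m)) else as.character(chrom),
    pos = if (is.null(pos)) seq_len(m) * 1e6 else pos,
    effect_allele = if (is.null(ea)) rep("A", m) else ea,
    other_allele = if (is.null(oa)) rep("G", m) else oa,
    beta = betas,
    eaf = if (is.null(eaf)) rep(0.3, m) else eaf,
    annotation = if (is.null(annotation)) rep("unknown", m) else annotation,
    stringsAsFactors = FALSE)
  if (!is.null(pval)) s$pval <- pval
  new("InstrumentSet", snps = s)
}

makeGenotypes <- function(n, maf, seed = 1) {
  withr::with_seed(seed, {
    m <- length(maf)
    g <- vapply(maf, function(p) rbinom(n, 1, p) + rbinom(n, 1, p),
                numeric(n))
    colnames(g) <- sprintf("s%02d", seq_len(m))
    g
  })
}

makeCovariates <- function(n, seed = 1) {
  withr::with_seed(seed + 17, {
    cov <- data.frame(age = round(runif(n, 40, 69)), sex = 0L)
    for (k in paste0("PC", 1:10)) cov[[k]] <- rnorm(n)
    cov
  })
}

# random harmonized pair tables for estimator/oracle comparisons
makePairs <- function(k, seed = 1, trueEffect = 0.05, pleioMean = 0,
                      pleioSD = 0) {
  withr::with_seed(seed, {
    bxTrue <- abs(rnorm(k, 0.1, 0.05)) + 0.02
    seX <- runif(k, 0.003, 0.01)
    seY <- runif(k, 0.005, 0.02)
    alpha <- rnorm(k, pleioMean, pleioSD)
    data.frame(snp = sprintf("s%02d", seq_len(k)), eaf = runif(k, .1, .9),
               beta_x = bxTrue + rnorm(k, 0, seX), se_x = seX,
               beta_y = trueEffect * bxTrue + alpha + rnorm(k, 0, seY),
               se_y = seY, stringsAsFactors = FALSE)
  })
}
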