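#' Run the full MR-pheWAS pipeline on one configuration
#'
#' Composes the whole analysis end to end on synthetic data: simulate the
#' female cohort and the male negative-control cohort; build the full,
#' pruned, DDR and non-DDR genetic risk scores; scan the phenome in both
#' sexes; derive FDR and Bonferroni thresholds; run one-sample two-stage
#' MR on the FDR-significant continuous and binary fields; simulate
#' replication GWAS summary statistics, harmonize them and run the
#' two-sample estimator suite; and summarise findings by category and by
#' sex. Idempotent under a fixed seed. When \code{outDir} is given, every
#' stage's table is written as TSV and a manifest (stage status, counts,
#' file digests, seed) as YAML.
#'
#' @param config a \code{SimConfig} or path to a YAML config file.
#' @param outDir optional output directory.
#' @param seed overrides the config seed when given.
#' @param pruneR2Max,pruneWindowBp pruning parameters for the
#'   sensitivity score (defaults 0.001 and 1e7).
#' @param nBoot bootstrap replicates for median/mode SEs.
#' @return list with \code{manifest} plus all stage outputs
#'   (\code{cohortFemale}, \code{cohortMale}, \code{instruments},
#'   \code{scores}, \code{scanFemale}, \code{scanMale},
#'   \code{thresholdsFemale}, \code{thresholdsMale}, \code{mrOneSample},
#'   \code{mrTwoSample}, \code{categorySummary}, \code{sexComparison}).
#' @export
runPipeline <- function(config, outDir = NULL, seed = NULL,
                        pruneR2Max = 0.001, pruneWindowBp = 1e7,
                        nBoot = 200L) {
  if (is.character(config)) config <- readSimConfig(config)
  stopifnot(is(config, "SimConfig"))
  if (!is.null(seed)) config@seed <- as.integer(seed)
  manifest <- list(seed = config@seed, stages = list(), counts = list(),
                   files = list())
  out <- list()
  stage <- function(name, expr) {
    res <- tryCatch(list(ok = TRUE, value = force(expr)),
                    error = function(e)
                      list(ok = FALSE, value = conditionMessage(e)))
    manifest$stages[[name]] <<- if (res$ok) "ok"
      else paste("failed:", res$value)
    if (!res$ok) message("stage ", name, " failed: ", res$value)
    if (res$ok) res$value else NULL
  }

  simF <- stage("simulate_female", simulateCohort(config))
  simM <- stage("simulate_male", simulateMaleCohort(config))
  if (is.null(simF) || is.null(simM)) {
    manifest$stages$downstream <- "skipped"
    return(list(manifest = manifest))
  }
  out$cohortFemale <- simF$cohort
  out$cohortMale <- simM$cohort
  out$instruments <- simF$instruments
  out$truth <- simF$truth

  gF <- genotypes(simF$cohort)
  gM <- genotypes(simM$cohort)
  scores <- stage("grs", {
    full <- computeGRS(gF, simF$instruments)
    pruned <- pruneInstruments(simF$instruments, gF,
                               windowBp = pruneWindowBp, r2Max = pruneR2Max)
    list(full = full,
         pruned = if (nInstruments(pruned)) computeGRS(gF, pruned)
                  else NULL,
         prunedSet = pruned,
         ddr = {
           s <- suppressWarnings(stratifyInstruments(simF$instruments,
                                                     "DDR"))
           if (nInstruments(s)) computeGRS(gF, s) else NULL
         },
         nonddr = {
           s <- suppressWarnings(stratifyInstruments(simF$instruments,
                                                     "non-DDR"))
           if (nInstruments(s)) computeGRS(gF, s) else NULL
         },
         male = computeGRS(gM, simF$instruments))
  })
  out$scores <- scores
  if (is.null(scores)) return(c(out, list(manifest = manifest)))

  scanF <- stage("scan_female",
    runPhenomeScan(scores$full, phenome(simF$cohort),
                   phenomeMeta(simF$cohort), covariates(simF$cohort)))
  scanM <- stage("scan_male",
    runPhenomeScan(scores$male, phenome(simM$cohort),
                   phenomeMeta(simM$cohort), covariates(simM$cohort)))
  out$scanFemale <- scanF
  out$scanMale <- scanM

  thrF <- thrM <- NULL
  if (!is.null(scanF)) {
    convF <- scanF[scanF$converged, ]
    thrF <- stage("thresholds_female",
      fdrRankThreshold(setNames(convF$pvalue, convF$field_id)))
    manifest$counts$fields_scanned_female <-
      nrow(scanF) + nrow(attr(scanF, "skipped"))
    manifest$counts$results_female <- nrow(scanF)
    manifest$counts$skipped_female <- nrow(attr(scanF, "skipped"))
    manifest$counts$fdr_significant_female <-
      length(thrF$significant_fdr %||% integer(0))
    manifest$counts$bonferroni_significant_female <-
      length(thrF$significant_bonferroni %||% integer(0))
  }
  if (!is.null(scanM)) {
    convM <- scanM[scanM$converged, ]
    thrM <- stage("thresholds_male",
      fdrRankThreshold(setNames(convM$pvalue, convM$field_id)))
  }
  out$thresholdsFemale <- thrF
  out$thresholdsMale <- thrM

  if (!is.null(thrF) && length(thrF$significant_fdr)) {
    out$mrOneSample <- stage("mr_onesample", {
      first <- predictExposure(scores$full, exposure(simF$cohort),
                               covariates(simF$cohort))
      sig <- scanF[scanF$field_id %in% thrF$significant_fdr &
                   scanF$resolved_type %in% c("continuous", "binary"), ]
      do.call(rbind, lapply(seq_len(nrow(sig)), function(i) {
        est <- twoStageEstimate(first$fitted,
                                phenome(simF$cohort)[[sig$field_id[i]]],
                                sig$resolved_type[i],
                                covariates(simF$cohort))
        cbind(field_id = sig$field_id[i], as.data.frame(est))
      }))
    })
  }

  out$mrTwoSample <- stage("mr_twosample", {
    effects <- simF$truth$traitEffects
    target <- names(effects)[which.max(abs(effects))]
    ss <- simulateSummaryStats(simF$instruments,
                               trueEffect = effects[[target]],
                               pleiotropyMode = config@pleiotropyMode,
                               pleiotropyMean = config@pleiotropyMean,
                               pleiotropySd = config@pleiotropySd,
                               scrambleAlleles = TRUE,
                               seed = config@seed)
    harm <- harmonizeSumstats(ss$exposure, ss$outcome)
    cbind(outcome = target,
          mrSuite(harm$pairs, nBoot = nBoot, seed = config@seed))
  })

  if (!is.null(scanF) && !is.null(thrF))
    out$categorySummary <- stage("category_summary",
                                 categorySummary(scanF, thrF))
  if (!is.null(scanF) && !is.null(scanM) && !is.null(thrF) &&
      !is.null(thrM))
    out$sexComparison <- stage("compare_sexes",
                               compareSexes(scanF, scanM, thrF, thrM))

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeCohort(simF$cohort, file.path(outDir, "cohort_female"))
    writeCohort(simM$cohort, file.path(outDir, "cohort_male"))
    writeInstruments(simF$instruments,
                     file.path(outDir, "instruments.tsv"))
    fwriteTSV(data.frame(score = as.numeric(scores$full)),
              file.path(outDir, "scores.tsv"))
    if (!is.null(scanF)) {
      fwriteTSV(scanF, file.path(outDir, "scan_female.tsv"))
      fwriteTSV(qqData(scanF$pvalue[scanF$converged]),
                file.path(outDir, "qq_female.tsv"))
    }
    if (!is.null(scanM)) fwriteTSV(scanM, file.path(outDir, "scan_male.tsv"))
    if (!is.null(out$mrOneSample))
      fwriteTSV(out$mrOneSample, file.path(outDir, "mr1_results.tsv"))
    if (!is.null(out$mrTwoSample))
      fwriteTSV(out$mrTwoSample, file.path(outDir, "mr2_results.tsv"))
    if (!is.null(out$categorySummary))
      fwriteTSV(out$categorySummary,
                file.path(outDir, "category_summary.tsv"))
    if (!is.null(out$sexComparison))
      fwriteTSV(out$sexComparison, file.path(outDir, "sex_comparison.tsv"))
    files <- list.files(outDir, recursive = TRUE, full.names = TRUE)
    files <- files[basename(files) != "manifest.yaml"]
    manifest$files <- as.list(setNames(unname(tools::md5sum(files)),
                                       substring(files,
                                                 nchar(outDir) + 2L)))
    yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))
  }
  c(out, list(manifest = manifest))
}

#' Count significant findings per trait category
#'
#' @param results scan result data.frame (with \code{category} column).
#' @param thresholds output of \code{\link{fdrRankThreshold}} on these
#'   results.
#' @return data.frame with per-category counts of FDR- and
#'   Bonferroni-significant findings; counts sum to the threshold sets.
#' @export
categorySummary <- function(results, thresholds) {
  cats <- sort(unique(results$category))
  fdrSet <- thresholds$significant_fdr
  bonSet <- thresholds$significant_bonferroni
  data.frame(
    category = cats,
    n_fields = vapply(cats, function(ct)
      sum(results$category == ct), 0L),
    n_fdr = vapply(cats, function(ct)
      sum(results$field_id %in% fdrSet & results$category == ct), 0L),
    n_bonferroni = vapply(cats, function(ct)
      sum(results$field_id %in% bonSet & results$category == ct), 0L),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify fields by sex-specific significance
#'
#' Per-field classification at the FDR and Bonferroni thresholds:
#' \code{"female-only"}, \code{"male-only"}, \code{"both"} or
#' \code{"neither"}. Exposure-mediated effects are expected female-only;
#' channels shared between the sexes (direct pleiotropy, biological aging)
#' appear in both.
#'
#' @param resultsFemale,resultsMale scan results over the same field
#'   universe.
#' @param thresholdsFemale,thresholdsMale matching
#'   \code{\link{fdrRankThreshold}} outputs.
#' @return data.frame with \code{field_id}, \code{class_fdr},
#'   \code{class_bonferroni}.
#' @export
compareSexes <- function(resultsFemale, resultsMale, thresholdsFemale,
                         thresholdsMale) {
  uf <- sort(resultsFemale$field_id)
  um <- sort(resultsMale$field_id)
  if (!identical(uf, um)) {
    diff <- c(setdiff(uf, um), setdiff(um, uf))
    stop("field universes differ between scans: ",
         paste(diff, collapse = ", "), call. = FALSE)
  }
  classify <- function(fid, setF, setM) {
    inF <- fid %in% setF
    inM <- fid %in% setM
    ifelse(inF & inM, "both",
           ifelse(inF, "female-only", ifelse(inM, "male-only", "neither")))
  }
  data.frame(
    field_id = uf,
    class_fdr = classify(uf, thresholdsFemale$significant_fdr,
                         thresholdsMale$significant_fdr),
    class_bonferroni = classify(uf,
                                thresholdsFemale$significant_bonferroni,
                                thresholdsMale$significant_bonferroni),
    stringsAsFactors = FALSE)
}
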