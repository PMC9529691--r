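#' Resolve a phenome field's variable type
#'
#' Declared non-auto types pass through after validation (a declared binary
#' field must show exactly two observed levels). Automatic resolution uses
#' the rule table: 2 distinct observed values -> binary; numeric with >= 20
#' distinct values -> continuous; numeric with 3-19 distinct values ->
#' ordered categorical (natural numeric order); non-numeric with >= 3
#' levels -> unordered categorical. A single distinct value is not
#' analysable and raises a condition of class \code{mrphewas_skip}.
#'
#' @param values the field's column (missing values ignored).
#' @param meta list or one-row data.frame with \code{declared_type} and
#'   optionally \code{ordered_levels}; defaults to auto.
#' @param continuousMin minimum distinct numeric values for "continuous"
#'   under auto typing (default 20).
#' @return one of "continuous", "binary", "ordered_categorical",
#'   "unordered_categorical".
#' @export
resolveTraitType <- function(values, meta = list(declared_type = "auto"),
                             continuousMin = 20L) {
  v <- values[!is.na(values)]
  if (!length(v)) stop("field empty after missing removal", call. = FALSE)
  nd <- length(unique(v))
  declared <- meta$declared_type %||% "auto"
  if (nd == 1L)
    stop(structure(class = c("mrphewas_skip", "error", "condition"),
                   list(message = "single distinct value", call = NULL)))
  if (declared != "auto") {
    if (declared == "binary" && nd != 2L)
      stop("field declared binary but has ", nd, " observed levels",
           call. = FALSE)
    return(declared)
  }
  if (nd == 2L) return("binary")
  if (is.numeric(v)) {
    if (nd >= continuousMin) return("continuous")
    return("ordered_categorical")
  }
  "unordered_categorical"
}

#' Inverse normal rank transform
#'
#' Maps each non-missing value to the standard-normal quantile of
#' \code{(rank - 0.5) / m}, where \code{m} is the number of non-missing
#' values and tied values receive their average rank. Missing values stay
#' missing; the transform is monotone in the input.
#'
#' @param values numeric vector.
#' @return transformed vector of the same length.
#' @examples
#' inverseNormalTransform(c(1, 2, 3))  # qnorm(c(1, 3, 5) / 6)
#' @export
inverseNormalTransform <- function(values) {
  ok <- !is.na(values)
  v <- values[ok]
  if (length(v) < 2) stop("need >= 2 non-missing values", call. = FALSE)
  if (length(unique(v)) == 1L)
    stop(structure(class = c("mrphewas_skip", "error", "condition"),
                   list(message = "all values identical", call = NULL)))
  r <- rank(v, ties.method = "average")
  out <- values
  out[ok] <- qnorm((r - 0.5) / length(v))
  out
}

# fit one field; returns a one-row result data.frame or signals skip
fitOneField <- function(y, type, score, covars, minCases, fieldId,
                        category) {
  X <- data.frame(score = score, covars)
  res <- data.frame(field_id = fieldId, resolved_type = type,
                    model = NA_character_, estimate = NA_real_,
                    se = NA_real_, pvalue = NA_real_,
                    n = length(y), n_cases = NA_integer_,
                    converged = FALSE, category = category,
                    stringsAsFactors = FALSE)
  fitOnce <- function(sc) {
    X$score <- sc
    dat <- cbind(y = y, X)
    # formula built here so model post-processing (vcov/summary) can
    # re-evaluate `dat` from the formula environment
    fml <- stats::as.formula(paste("y ~ score +",
                                   paste(covariateColumns(),
                                         collapse = " + ")))
    switch(type,
      continuous = {
        fit <- lm(fml, data = dat)
        cf <- summary(fit)$coefficients["score", ]
        list(model = "linear", estimate = cf[1], se = cf[2], p = cf[4],
             cases = NA_integer_)
      },
      binary = {
        lev <- sort(unique(y))
        yb <- as.integer(y == lev[2])
        cases <- min(sum(yb), sum(1 - yb))
        if (cases < minCases)
          stop(structure(class = c("mrphewas_skip", "error", "condition"),
                         list(message = sprintf("fewer than %d cases", minCases),
                              call = NULL)))
        dat$y <- yb
        fit <- glm(fml, data = dat, family = binomial())
        if (!fit$converged) stop("glm did not converge", call. = FALSE)
        cf <- summary(fit)$coefficients["score", ]
        list(model = "logistic", estimate = cf[1], se = cf[2], p = cf[4],
             cases = sum(yb))
      },
      ordered_categorical = {
        dat$y <- factor(y, ordered = TRUE)
        fit <- MASS::polr(fml, data = dat, Hess = TRUE)
        cf <- summary(fit)$coefficients["score", ]
        z <- cf[1] / cf[2]
        list(model = "ordered_logistic", estimate = cf[1], se = cf[2],
             p = 2 * pnorm(-abs(z)), cases = NA_integer_)
      },
      unordered_categorical = {
        dat$y <- factor(y)
        fit1 <- nnet::multinom(fml, data = dat, trace = FALSE,
                               maxit = 200)
        fml0 <- stats::as.formula(paste("y ~",
                   paste(covariateColumns(), collapse = " + ")))
        fit0 <- nnet::multinom(fml0, data = dat, trace = FALSE,
                               maxit = 200)
        lrt <- fit0$deviance - fit1$deviance
        df <- length(levels(dat$y)) - 1L
        cf <- coef(fit1)
        sc <- cf[, "score"]
        sesc <- tryCatch(summary(fit1)$standard.errors[, "score"],
                         error = function(e) rep(NA_real_, length(sc)))
        j <- which.max(abs(sc))
        list(model = "multinomial", estimate = sc[j], se = sesc[j],
             p = pchisq(lrt, df, lower.tail = FALSE), cases = NA_integer_)
      })
  }
  out <- tryCatch(fitOnce(score), mrphewas_skip = function(e) e,
                  error = function(e) e)
  if (inherits(out, "mrphewas_skip")) stop(out)
  if (inherits(out, "error")) {
    # one retry with a rescaled score, then report non-convergence
    out <- tryCatch(fitOnce(drop(scale(score))),
                    mrphewas_skip = function(e) e, error = function(e) e)
    if (inherits(out, "mrphewas_skip")) stop(out)
    if (inherits(out, "error")) {
      res$model <- switch(type, continuous = "linear", binary = "logistic",
                          ordered_categorical = "ordered_logistic",
                          unordered_categorical = "multinomial")
      return(res)
    }
    out$note <- "rescaled"
  }
  res$model <- out$model
  res$estimate <- unname(out$estimate)
  res$se <- unname(out$se)
  res$pvalue <- unname(out$p)
  res$n_cases <- out$cases
  res$converged <- TRUE
  res
}

#' Run the automated phenome-wide scan
#'
#' For each phenome field: restrict to complete cases over score, field and
#' covariates; resolve the variable type; inverse-normal rank transform
#' continuous fields; and regress the outcome on the score adjusted for age
#' and the first ten genetic principal components, routing by type to
#' linear, logistic, ordered-logistic (proportional odds) or multinomial
#' regression. Multinomial fields get a single per-field p-value from the
#' likelihood-ratio test against the score-free model, with the estimate
#' reported as the largest-magnitude category contrast. Estimates are mean
#' differences (transformed scale) or log-odds per unit increase in the
#' score. Sex is never a covariate: scans are run within one sex.
#'
#' Non-analysable fields (constant, too few cases, irrecoverable fit
#' failure after one rescaled retry) are skipped and logged, never dropped
#' silently: \code{nrow(result) + nrow(attr(result, "skipped"))} equals the
#' number of input fields.
#'
#' @param score a \code{ScoreVector} (or numeric vector), row-aligned with
#'   \code{phenome} and \code{covariates}.
#' @param phenome data.frame of outcome columns.
#' @param meta per-field metadata (\code{field_id}, \code{declared_type},
#'   \code{category}); defaults to auto-typing every phenome column.
#' @param covariates data.frame containing \code{age} and
#'   \code{PC1}..\code{PC10}.
#' @param minCases binary fields with fewer cases (in the rarer class) are
#'   skipped (default 10, a separation guard).
#' @return data.frame with one row per analysed field (\code{field_id},
#'   \code{resolved_type}, \code{model}, \code{estimate}, \code{se},
#'   \code{pvalue}, \code{n}, \code{n_cases}, \code{converged},
#'   \code{category}), with skipped fields in \code{attr(, "skipped")}.
#' @export
runPhenomeScan <- function(score, phenome, meta = NULL, covariates,
                           minCases = 10L) {
  score <- as.numeric(score)
  if (length(score) != nrow(phenome) ||
      nrow(phenome) != nrow(covariates))
    stop("score, phenome and covariates must be row-aligned", call. = FALSE)
  checkCovariates(covariates)
  if (is.null(meta))
    meta <- data.frame(field_id = colnames(phenome),
                       declared_type = "auto", category = "unspecified",
                       stringsAsFactors = FALSE)
  covars <- covariates[, covariateColumns(), drop = FALSE]
  results <- list(); skipped <- list()
  for (k in seq_len(nrow(meta))) {
    fid <- meta$field_id[k]
    category <- meta$category[k] %||% "unspecified"
    yAll <- phenome[[fid]]
    ok <- complete.cases(score, yAll, covars)
    y <- yAll[ok]
    row <- tryCatch({
      type <- resolveTraitType(y, meta[k, ])
      yUse <- if (type == "continuous") inverseNormalTransform(y) else y
      fitOneField(yUse, type, score[ok], covars[ok, , drop = FALSE],
                  minCases, fid, category)
    },
    mrphewas_skip = function(e) {
      structure(list(field_id = fid, reason = conditionMessage(e)),
                class = "scan_skip")
    })
    if (inherits(row, "scan_skip")) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(field_id = row$field_id, reason = row$reason,
                   stringsAsFactors = FALSE)
    } else results[[length(results) + 1L]] <- row
  }
  out <- if (length(results)) do.call(rbind, results)
         else data.frame(field_id = character(0))
  rownames(out) <- NULL
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped)
    else data.frame(field_id = character(0), reason = character(0))
  out
}
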