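#' First stage of one-sample MR: genetically predicted exposure
#'
#' Linear regression of the exposure on the genetic risk score plus age and
#' the first ten genetic principal components; returns the fitted
#' ("genetically predicted") exposure together with instrument-strength
#' diagnostics.
#'
#' @param score a \code{ScoreVector} (or numeric), row-aligned.
#' @param exposure exposure vector (years).
#' @param covariates data.frame with \code{age}, \code{PC1}..\code{PC10}.
#' @return list with \code{fitted} (NA where any input is missing),
#'   \code{coefficients} (first-stage coefficients), \code{strength}
#'   (see \code{\link{instrumentStrength}}) and \code{n}.
#' @export
predictExposure <- function(score, exposure, covariates) {
  score <- as.numeric(score)
  if (length(score) != length(exposure) ||
      length(score) != nrow(covariates))
    stop("score, exposure and covariates must be row-aligned",
         call. = FALSE)
  checkCovariates(covariates)
  dat <- data.frame(exposure = exposure, score = score,
                    covariates[, covariateColumns(), drop = FALSE])
  ok <- complete.cases(dat)
  if (sum(ok) < 3) stop("need >= 3 complete rows", call. = FALSE)
  if (var(score[ok]) == 0)
    stop("weak instrument: score has zero variance", call. = FALSE)
  fml <- stats::as.formula(paste("exposure ~ score +",
                                 paste(covariateColumns(),
                                       collapse = " + ")))
  fit <- lm(fml, data = dat[ok, ])
  fitted <- rep(NA_real_, length(score))
  fitted[ok] <- fit$fitted.values
  list(fitted = fitted, coefficients = coef(fit),
       strength = instrumentStrength(score[ok], exposure[ok]),
       n = sum(ok))
}

#' Second stage of one-sample MR
#'
#' Regresses the outcome on the genetically predicted exposure plus the
#' same covariates -- linear for continuous outcomes, logistic for binary
#' -- and reports the causal estimate per year \emph{decrease} of the
#' exposure (the default sign convention; \code{sign = "increase"}
#' reverses it). The 95\% CI uses the large-sample normal approximation.
#' Standard errors are the plain second-stage model SEs, unadjusted for
#' first-stage uncertainty; a note in \code{extra} flags this.
#'
#' @param predicted fitted exposure from \code{\link{predictExposure}}.
#' @param outcome outcome column (continuous, or binary with both classes
#'   present).
#' @param outcomeType "continuous" or "binary".
#' @param covariates covariate table as in the first stage.
#' @param sign "decrease" (default) or "increase".
#' @return an \code{MREstimate} (log-odds scale for binary outcomes).
#' @export
twoStageEstimate <- function(predicted, outcome,
                             outcomeType = c("continuous", "binary"),
                             covariates, sign = c("decrease", "increase")) {
  outcomeType <- match.arg(outcomeType)
  sign <- match.arg(sign)
  checkCovariates(covariates)
  dat <- data.frame(outcome = outcome, predicted = predicted,
                    covariates[, covariateColumns(), drop = FALSE])
  ok <- complete.cases(dat)
  dat <- dat[ok, ]
  fml <- stats::as.formula(paste("outcome ~ predicted +",
                                 paste(covariateColumns(),
                                       collapse = " + ")))
  if (outcomeType == "binary") {
    lev <- sort(unique(dat$outcome))
    if (length(lev) != 2L)
      stop("binary outcome must have both classes present", call. = FALSE)
    dat$outcome <- as.integer(dat$outcome == lev[2])
    fit <- glm(fml, data = dat, family = binomial())
    conv <- fit$converged
  } else {
    fit <- lm(fml, data = dat)
    conv <- TRUE
  }
  cf <- summary(fit)$coefficients["predicted", ]
  est <- if (sign == "decrease") -cf[1] else cf[1]
  out <- makeMREstimate(
    method = paste0("two-stage (",
                    if (outcomeType == "binary") "logistic" else "linear",
                    ")"),
    estimate = unname(est), se = unname(cf[2]), nObs = nrow(dat),
    sign = sign,
    extra = list(converged = conv,
                 note = "second-stage SE unadjusted for first-stage uncertainty"))
  out
}
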