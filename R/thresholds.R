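#' Bonferroni-corrected p-value threshold
#'
#' @param n number of tests performed (>= 1).
#' @param alpha family-wise level (default 0.05).
#' @return \code{alpha / n}.
#' @examples
#' bonferroniThreshold(18961)  # 2.64e-6 at 3 significant figures
#' @export
bonferroniThreshold <- function(n, alpha = 0.05) {
  if (length(n) != 1L || !is.finite(n) || n < 1)
    stop("n must be a single count >= 1", call. = FALSE)
  alpha / n
}

#' Rank-based 5\% false discovery rate threshold
#'
#' P-values are ranked ascending; the threshold is
#' \code{P_t(rank) = alpha * rank / n} where \code{rank} is the largest
#' rank position whose p-value is strictly below \code{alpha * rank / n}
#' (the step-up rule; rank 0 when no p-value qualifies). Final membership
#' uses \code{p <= P_t}, so reported significant sets are closed at the
#' threshold; set \code{strictMembership = TRUE} for strict inequality.
#' Tied p-values share the rule's decision through the last index at the
#' tied value.
#'
#' @param pvalues numeric p-values in [0, 1], optionally named by field id.
#' @param alpha target FDR (default 0.05).
#' @param strictMembership use \code{p < P_t} for the significant set.
#' @return list with \code{n}, \code{alpha}, \code{bonferroni_threshold},
#'   \code{fdr_threshold}, \code{fdr_rank}, and the significant index/name
#'   sets at each threshold (\code{significant_fdr},
#'   \code{significant_bonferroni}).
#' @export
fdrRankThreshold <- function(pvalues, alpha = 0.05,
                             strictMembership = FALSE) {
  p <- as.numeric(pvalues)
  if (!length(p)) stop("need at least one p-value", call. = FALSE)
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  n <- length(p)
  ps <- sort(p)
  pass <- ps < alpha * seq_len(n) / n
  fdrRank <- if (any(pass)) max(which(pass)) else 0L
  pt <- alpha * fdrRank / n
  bon <- bonferroniThreshold(n, alpha)
  inSet <- function(thr) {
    hit <- if (strictMembership) p < thr else p <= thr
    if (thr == 0) hit <- rep(FALSE, n)
    if (!is.null(names(pvalues))) names(pvalues)[hit] else which(hit)
  }
  list(n = n, alpha = alpha, bonferroni_threshold = bon,
       fdr_threshold = pt, fdr_rank = as.integer(fdrRank),
       significant_fdr = inSet(pt),
       significant_bonferroni = inSet(bon))
}

#' Expected/observed quantile pairs for a QQ plot of p-values
#'
#' Pairs the i-th smallest observed \code{-log10} p with the uniform
#' expectation \code{-log10((i - 0.5) / n)}, and attaches the Bonferroni
#' and rank-FDR reference thresholds as attributes. Zero p-values are
#' floored at the smallest positive double (with a message).
#'
#' @param pvalues p-values.
#' @param alpha level for the two reference thresholds.
#' @return data.frame with \code{expected} and \code{observed} columns
#'   (ascending expected), attributes \code{bonferroni} and \code{fdr}.
#' @export
qqData <- function(pvalues, alpha = 0.05) {
  p <- as.numeric(pvalues)
  if (!length(p)) stop("need at least one p-value", call. = FALSE)
  if (any(p == 0)) {
    message("flooring ", sum(p == 0), " zero p-value(s) at the smallest ",
            "positive double")
    p[p == 0] <- .Machine$double.xmin
  }
  thr <- fdrRankThreshold(p, alpha)
  n <- length(p)
  out <- data.frame(expected = -log10((seq_len(n) - 0.5) / n),
                    observed = -log10(sort(p)))
  out <- out[order(out$expected), ]
  rownames(out) <- NULL
  attr(out, "bonferroni") <- thr$bonferroni_threshold
  attr(out, "fdr") <- thr$fdr_threshold
  out
}
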