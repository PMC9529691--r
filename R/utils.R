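# Internal helpers shared across modules.

# Deterministic substream seed derivation: one user-facing seed, independent
# per-component streams so partial re-runs reproduce. Polynomial rolling
# hash over the component label (base 131, modulus 2^31 - 1) so distinct
# labels get distinct streams; result stays below 2^31 - 1.
substreamSeed <- function(seed, component) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  M <- 2147483647
  h <- abs(seed) %% M
  for (code in utf8ToInt(as.character(component)))
    h <- (h * 131 + code) %% M
  as.integer((h * 48271 + 12345) %% M)
}

withSubstream <- function(seed, component, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(substreamSeed(seed, component))
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

# weighted standard deviation (used by the mode estimator's bandwidth rule)
weightedSD <- function(x, w) {
  w <- w / sum(w)
  mu <- sum(w * x)
  sqrt(sum(w * (x - mu)^2) / (1 - sum(w^2)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assertNumericIn <- function(x, lo, hi, what, open = FALSE) {
  bad <- if (open) any(x <= lo | x >= hi, na.rm = TRUE) else any(x < lo | x > hi, na.rm = TRUE)
  if (any(!is.finite(x[!is.na(x)])) || bad)
    stop(sprintf("%s must lie in %s%g, %g%s", what,
                 if (open) "(" else "[", lo, hi, if (open) ")" else "]"),
         call. = FALSE)
  invisible(x)
}

# PC column names used throughout the adjustment set
pcCols <- function(k = 10L) paste0("PC", seq_len(k))

covariateColumns <- function() c("age", pcCols())

checkCovariates <- function(covariates) {
  need <- covariateColumns()
  miss <- setdiff(need, colnames(covariates))
  if (length(miss))
    stop("covariate table is missing required columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  invisible(covariates)
}
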