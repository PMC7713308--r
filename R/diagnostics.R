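#' Gelman-Rubin potential scale reduction factor
#'
#' The classic between/within-chain variance ratio: with m chains of length
#' n, within-chain variance W and between-chain variance B (of the chain
#' means), the pooled posterior variance estimate is
#' \eqn{\hat V = (n-1)/n\, W + B/n \cdot n = (n-1)/n\,W + B} and the shrink
#' factor is \eqn{\hat R = \sqrt{\hat V / W}}. Values near 1 indicate the
#' chains have mixed over the same distribution.
#'
#' The implementation follows the sampling-variability-corrected estimator
#' (the one convergence packages report): the pooled variance estimate adds
#' the between-chain term inflated by `(1 + 1/m)`, and the ratio carries the
#' `(d + 3)/(d + 1)` degrees-of-freedom correction, floored at 1 so that
#' identical chains report exactly 1.
#'
#' @param chains list of numeric vectors (one per chain, equal length).
#' @return the shrink factor (>= 1); `Inf` for degenerate chains with zero
#'   within-chain variance but differing means.
#' @export
gelman_rubin <- function(chains) {
  stopifnot(is.list(chains), length(chains) >= 2)
  n <- unique(lengths(chains))
  stopifnot(length(n) == 1, n >= 2)
  m <- length(chains)
  xbar <- vapply(chains, mean, 0)
  s2 <- vapply(chains, stats::var, 0)
  W <- mean(s2)
  B <- n * stats::var(xbar)
  if (W == 0) return(if (B == 0) 1 else Inf)
  sigma2 <- (n - 1) / n * W + B / n
  V <- sigma2 + B / (m * n)
  ## method-of-moments df of the variance estimate
  var_w <- stats::var(s2) / m
  var_b <- 2 * B^2 / (m - 1)
  cov_wb <- (n / m) * (stats::cov(s2, xbar^2) - 2 * mean(xbar) * stats::cov(s2, xbar))
  var_V <- ((n - 1)^2 * var_w + (1 + 1 / m)^2 * var_b +
            2 * (n - 1) * (1 + 1 / m) * cov_wb) / n^2
  d <- if (is.finite(var_V) && var_V > 0) 2 * V^2 / var_V else Inf
  corr <- if (is.finite(d)) (d + 3) / (d + 1) else 1
  max(1, sqrt(corr * V / W))
}

#' MCMC convergence diagnostics
#'
#' Computes, per parameter, the Gelman-Rubin shrink factor, a crude effective
#' sample size from the lag autocorrelation of the pooled chain, and the
#' lag-1 autocorrelation. With a single chain the shrink factor is undefined
#' and reported as `NA` rather than silently.
#'
#' @param chains list of matrices (iterations x parameters), one per chain,
#'   with matching columns.
#' @param threshold shrink-factor level above which a parameter is flagged.
#' @return object of class `convergence_report`: data.frame `report` with
#'   columns `shrink`, `ess`, `acf1`, and logical `converged`.
#' @export
diagnose <- function(chains, threshold = 1.1) {
  if (is.matrix(chains)) chains <- list(chains)
  stopifnot(is.list(chains), length(chains) >= 1)
  chains <- lapply(chains, as.matrix)
  p <- ncol(chains[[1]])
  nm <- colnames(chains[[1]]) %||% paste0("par", seq_len(p))
  shrink <- ess <- acf1 <- numeric(p)
  for (i in seq_len(p)) {
    pooled <- unlist(lapply(chains, function(m) m[, i]))
    if (length(chains) >= 2) {
      shrink[i] <- gelman_rubin(lapply(chains, function(m) m[, i]))
    } else shrink[i] <- NA_real_
    if (stats::sd(pooled) == 0) {
      acf1[i] <- 0; ess[i] <- length(pooled)
    } else {
      a <- stats::acf(pooled, plot = FALSE,
                      lag.max = min(100, length(pooled) - 1))$acf[-1]
      acf1[i] <- a[1]
      pos <- a[seq_len(max(1, which(a < 0)[1] - 1, na.rm = TRUE))]
      pos <- pos[!is.na(pos) & pos > 0]
      ess[i] <- length(pooled) / (1 + 2 * sum(pos))
    }
  }
  rep <- data.frame(parameter = nm, shrink = shrink, ess = ess, acf1 = acf1)
  flagged <- !is.na(shrink) & shrink > threshold
  structure(list(report = rep, threshold = threshold,
                 converged = !any(flagged),
                 flagged = nm[flagged]),
            class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat("MCMC convergence report (threshold", x$threshold, ")\n")
  print(transform(x$report, shrink = round(shrink, 3), ess = round(ess),
                  acf1 = round(acf1, 3)))
  if (!x$converged)
    cat("flagged (shrink >", x$threshold, "):",
        paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}
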