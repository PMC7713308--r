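#' @export
print.hssm <- function(x, ...) {
  cat("Switching state-space model fit\n")
  cat(sprintf("  segments: %d   time step: %g h   retained draws: %d (%d chain%s)\n",
              length(x$series), x$spec$dt, nrow(x$params), x$plan$n_chains,
              if (x$plan$n_chains > 1) "s" else ""))
  cm <- coef(x)
  cat(sprintf("  gamma (transit, ARS): %.3f, %.3f\n",
              cm["gamma_transit"], cm["gamma_ars"]))
  if (!is.null(x$convergence) && any(x$convergence$report$shrink > 1.1, na.rm = TRUE))
    cat("  WARNING: Gelman-Rubin shrink factor > 1.1 for some parameters\n")
  invisible(x)
}

#' Posterior parameter means
#' @param object an `hssm` fit.
#' @param ... unused.
#' @export
coef.hssm <- function(object, ...) colMeans(as.matrix(object$params[, 1:7]))

#' @export
summary.hssm <- function(object, ...) {
  p <- as.matrix(object$params[, 1:7])
  tab <- t(apply(p, 2, function(v)
    c(mean = mean(v), sd = stats::sd(v),
      `2.5%` = unname(stats::quantile(v, 0.025)),
      `97.5%` = unname(stats::quantile(v, 0.975)))))
  res <- list(params = tab, n_draws = nrow(p),
              n_segments = length(object$series),
              p_ars_overall = mean(unlist(lapply(object$series, `[[`, "p_ars"))),
              convergence = object$convergence,
              accept_rate = object$accept_rate)
  class(res) <- "summary.hssm"
  res
}

#' @export
print.summary.hssm <- function(x, ...) {
  cat("Posterior parameter summary (", x$n_draws, " draws, ",
      x$n_segments, " segments)\n\n", sep = "")
  print(round(x$params, 4))
  cat(sprintf("\nOverall mean P(ARS): %.3f\n", x$p_ars_overall))
  if (!is.null(x$convergence)) {
    cat("\nGelman-Rubin shrink factors:\n")
    print(round(x$convergence$report$shrink, 3))
  }
  invisible(x)
}

#' Export the estimated state series as a flat table
#'
#' One row per regular time step per segment, in the standard export layout:
#' `tag_id, segment, timestamp, lon, lat, lon_lo, lon_hi, lat_lo, lat_hi,
#' mean_b, p_ars, mode_state`.
#'
#' @param x an `hssm` fit.
#' @param row.names,optional,... passed through for the generic's signature.
#' @export
as.data.frame.hssm <- function(x, row.names = NULL, optional = FALSE, ...) {
  rows <- lapply(seq_along(x$series), function(s) {
    sr <- x$series[[s]]
    data.frame(tag_id = attr(sr, "tag_id"), segment = attr(sr, "segment"),
               timestamp = sr$time, lon = sr$lon, lat = sr$lat,
               lon_lo = sr$lon_lo, lon_hi = sr$lon_hi,
               lat_lo = sr$lat_lo, lat_hi = sr$lat_hi,
               mean_b = sr$mean_b, p_ars = sr$p_ars,
               mode_state = sr$mode_state, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- row.names
  out
}

#' Probability of area-restricted search
#'
#' The posterior mean behavioural state lies in [1, 2] because the state is
#' discrete but averaged over MCMC draws; subtracting 1 maps it to the
#' probability of ARS in [0, 1], with values near 1 indicating a high
#' probability that the animal was in ARS at that time step.
#'
#' @param x an `hssm` fit, a state-series data.frame with a `mean_b` column,
#'   or a numeric vector of posterior mean states.
#' @return numeric vector of ARS probabilities.
#' @export
prob_ars <- function(x) {
  mb <- if (inherits(x, "hssm")) unlist(lapply(x$series, `[[`, "mean_b"))
        else if (is.data.frame(x)) x$mean_b
        else x
  if (any(mb < 1 - 1e-9 | mb > 2 + 1e-9))
    stop("posterior mean state must lie in [1, 2]")
  pmin(pmax(mb - 1, 0), 1)
}

#' Extract one joint posterior draw of locations and states
#'
#' Returns the locations and discrete states of every segment for a single
#' retained MCMC draw, as used by the multiple-imputation habitat procedure.
#'
#' @param fit an `hssm` fit.
#' @param index retained-draw row index (1..total retained).
#' @return data.frame `tag_id, segment, time, lon, lat, b, chain, draw`.
#' @export
posterior_draws <- function(fit, index) {
  stopifnot(inherits(fit, "hssm"), index >= 1, index <= nrow(fit$params))
  rows <- lapply(seq_along(fit$series), function(s) {
    sr <- fit$series[[s]]
    st <- fit$draws$segments[[s]]
    data.frame(tag_id = attr(sr, "tag_id"), segment = attr(sr, "segment"),
               time = sr$time,
               lon = st$lon[index, ], lat = st$lat[index, ],
               b = st$b[index, ],
               chain = fit$draws$chain[index], draw = fit$draws$draw[index],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Plot an hSSSM fit
#'
#' Left panel: estimated track coloured by the probability of ARS (blue =
#' transit, red = ARS). Right panel: the ARS probability series per segment.
#'
#' @param x an `hssm` fit.
#' @param ... unused.
#' @export
plot.hssm <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  all <- as.data.frame(x)
  pal <- grDevices::colorRamp(c("#2166ac", "#b2182b"))
  cols <- grDevices::rgb(pal(all$p_ars) / 255)
  plot(all$lon, all$lat, type = "n", xlab = "lon", ylab = "lat",
       main = "estimated track")
  for (s in seq_along(x$series)) {
    sr <- x$series[[s]]
    graphics::lines(sr$lon, sr$lat, col = "grey70")
  }
  graphics::points(all$lon, all$lat, col = cols, pch = 16, cex = 0.5)
  plot(all$p_ars, type = "l", ylim = c(0, 1), xlab = "step",
       ylab = "P(ARS)", main = "behavioural state")
  graphics::abline(h = 0.5, lty = 3)
  invisible(x)
}
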