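#' Simulate Argos-like telemetry tracks with known ground truth
#'
#' Simulates, per animal, a two-state switching first-difference correlated
#' random walk on a regular step grid: the displacement at step t equals the
#' previous displacement scaled by the state's move persistence plus Gaussian
#' process noise,
#' \deqn{d_t = \gamma_{b_t} d_{t-1} + \epsilon_t,\quad \epsilon_t \sim N(0, \Sigma),}
#' with the discrete behavioural state \eqn{b_t \in \{1,2\}} (1 = transit,
#' 2 = ARS) following a first-order Markov chain. Observations are then
#' emitted at irregular times (exponential inter-arrival, zeroed inside any
#' scheduled transmission gaps), positioned by linear interpolation in time
#' between the flanking true steps, and perturbed by class-specific
#' heavy-tailed (t) Argos error.
#'
#' The process is simulated directly in lon/lat degrees, as bsam-style
#' state-space models operate; at mid-latitudes one degree of longitude is
#' shorter on the ground than one of latitude, so an isotropic `Sigma` in
#' degrees is mildly anisotropic in kilometres.
#'
#' @param config a [sim_config()].
#' @return a list with elements
#'   \item{observations}{data.frame of Argos-like fixes: `tag_id`, `time`
#'     (POSIXct UTC), `lc`, `lon`, `lat`, time-ordered within tag.}
#'   \item{truth}{object of class `sim_truth`: per-whale list with the
#'     regular-step `time`, `lon`, `lat`, states `b`, plus the config.}
#' @examples
#' sim <- simulate_tracks(sim_config(n_whales = 2, n_steps = 50, seed = 7))
#' table(sim$observations$lc)
#' @export
simulate_tracks <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_whales
  Tn <- config$n_steps
  dt <- config$dt
  L <- chol(config$Sigma)
  gam <- c(config$gamma_transit, config$gamma_ars)
  P <- config$switch_prob

  deploy_t <- sort(config$deploy_window[1] +
                   stats::runif(n) * as.numeric(difftime(config$deploy_window[2],
                                                         config$deploy_window[1], units = "secs")))
  truth <- vector("list", n)
  obs_list <- vector("list", n)

  for (w in seq_len(n)) {
    tag <- sprintf("sim%02d", w)
    ## latent states: stationary start, then Markov transitions
    b <- integer(Tn)
    off <- P[1, 2] + P[2, 1]
    pi1 <- if (off > 0) P[2, 1] / off else 0.5  # stationary P(transit)
    b[1] <- if (stats::runif(1) < pi1) 1L else 2L
    for (t in 2:Tn) b[t] <- if (stats::runif(1) < P[b[t - 1], 1]) 1L else 2L

    ## switching CRW in degrees
    x <- matrix(0, Tn, 2)
    x[1, ] <- c(config$deploy_lon, config$deploy_lat) + stats::rnorm(2, 0, config$deploy_spread)
    d_prev <- c(0, 0)
    for (t in 2:Tn) {
      eps <- as.numeric(stats::rnorm(2) %*% L)
      d <- gam[b[t]] * d_prev + eps
      x[t, ] <- x[t - 1, ] + d
      d_prev <- d
    }

    step_t <- deploy_t[w] + (seq_len(Tn) - 1) * dt * 3600
    span_h <- (Tn - 1) * dt

    ## irregular transmission times: exponential inter-arrivals
    t_obs <- cumsum(stats::rexp(ceiling(span_h / config$mean_obs_interval * 1.6) + 20,
                                rate = 1 / config$mean_obs_interval))
    t_obs <- t_obs[t_obs <= span_h]
    if (!is.null(config$gap_schedule) && !is.null(config$gap_schedule[[w]])) {
      g <- config$gap_schedule[[w]]
      for (r in seq_len(nrow(g)))
        t_obs <- t_obs[t_obs < g[r, 1] | t_obs > g[r, 1] + g[r, 2]]
    }
    m <- length(t_obs)
    if (m == 0) {
      obs_list[[w]] <- NULL
    } else {
      ## linear interpolation of the true path to observation times
      frac <- t_obs / dt
      k <- pmin(floor(frac) + 1, Tn - 1)
      j <- frac - (k - 1)
      lon_true <- (1 - j) * x[k, 1] + j * x[k + 1, 1]
      lat_true <- (1 - j) * x[k, 2] + j * x[k + 1, 2]
      lc <- sample(ARGOS_CLASSES, m, replace = TRUE, prob = config$class_mix)
      err <- .draw_argos_error(config$error_model, lc)
      obs_list[[w]] <- data.frame(tag_id = tag,
                                  time = deploy_t[w] + t_obs * 3600,
                                  lc = lc,
                                  lon = lon_true + err[, "lon"],
                                  lat = lat_true + err[, "lat"],
                                  stringsAsFactors = FALSE)
    }
    truth[[w]] <- list(tag_id = tag, time = step_t, lon = x[, 1], lat = x[, 2], b = b)
  }
  observations <- do.call(rbind, obs_list)
  rownames(observations) <- NULL
  list(observations = observations,
       truth = structure(list(whales = truth, config = config), class = "sim_truth"))
}
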