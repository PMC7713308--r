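#' Configuration for the synthetic Argos track generator
#'
#' Defines the ground-truth movement process (a two-state switching
#' first-difference correlated random walk), the Argos observation process
#' (irregular transmission times, quality-class mix, class-specific
#' heavy-tailed location error, scheduled transmission gaps) and the
#' deployment layout. The defaults emulate the study system the package was
#' built around: adult pygmy blue whales tagged in the Bonney Upwelling
#' (southern Australia) in January-March, transmitting on average once every
#' 2.3 h with occasional multi-day gaps, and alternating between directed
#' transit and area-restricted search (ARS) with multi-day dwell times.
#'
#' @param n_whales number of simulated animals.
#' @param n_steps regular true-process steps per animal (step = `dt` hours).
#' @param dt true-process step, hours.
#' @param deploy_window POSIXct length-2 vector; deployment times are spread
#'   uniformly across it.
#' @param deploy_lon,deploy_lat deployment centroid, degrees.
#' @param deploy_spread s.d. of deployment position jitter, degrees.
#' @param mean_obs_interval mean hours between transmissions (exponential
#'   inter-arrival times).
#' @param gap_schedule list (one element per whale) of two-column matrices
#'   `cbind(start_h, duration_h)` giving transmission gaps relative to that
#'   whale's deployment; `NULL` for no gaps. Explicit, not random, so
#'   segmentation tests are deterministic.
#' @param class_mix named probability vector over the 7 Argos classes.
#' @param gamma_transit,gamma_ars move persistence in each behavioural state;
#'   must satisfy `0 < gamma_ars < gamma_transit < 1`.
#' @param Sigma 2x2 positive-definite process covariance (degrees^2/step^2).
#' @param switch_prob 2x2 state transition matrix, rows (from transit, from
#'   ARS) summing to 1. Defaults give mean dwell ~4 days at 3-h steps.
#' @param error_model an [argos_error_model()].
#' @param seed integer seed; the generator is bit-reproducible given the seed.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_whales = 13,
                       n_steps = 500,
                       dt = 3,
                       deploy_window = as.POSIXct(c("2015-01-20", "2015-03-15"), tz = "UTC"),
                       deploy_lon = 139.6, deploy_lat = -38.6, deploy_spread = 0.4,
                       mean_obs_interval = 2.3,
                       gap_schedule = NULL,
                       class_mix = c("3" = 0.07, "2" = 0.10, "1" = 0.13, "0" = 0.15,
                                     "A" = 0.22, "B" = 0.28, "Z" = 0.05),
                       gamma_transit = 0.8, gamma_ars = 0.2,
                       Sigma = diag(c(0.05^2, 0.05^2)),
                       switch_prob = matrix(c(0.97, 0.03, 0.03, 0.97), 2, 2, byrow = TRUE),
                       error_model = argos_error_model(),
                       seed = 1L) {
  stopifnot(n_whales >= 1, n_steps >= 3, dt > 0, mean_obs_interval > 0)
  if (!(gamma_ars > 0 && gamma_transit < 1 && gamma_ars < gamma_transit))
    stop("need 0 < gamma_ars < gamma_transit < 1")
  stopifnot(all(dim(switch_prob) == c(2, 2)), all(switch_prob >= 0))
  if (max(abs(rowSums(switch_prob) - 1)) > 1e-8) stop("rows of switch_prob must sum to 1")
  stopifnot(all(dim(Sigma) == c(2, 2)))
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("Sigma must be positive definite")
  stopifnot(all(ARGOS_CLASSES %in% names(class_mix)))
  if (abs(sum(class_mix) - 1) > 1e-8) stop("class_mix must sum to 1")
  if (!is.null(gap_schedule)) stopifnot(length(gap_schedule) == n_whales)
  stopifnot(inherits(error_model, "argos_error_model"))
  structure(list(n_whales = n_whales, n_steps = n_steps, dt = dt,
                 deploy_window = .as_utc(deploy_window),
                 deploy_lon = deploy_lon, deploy_lat = deploy_lat,
                 deploy_spread = deploy_spread,
                 mean_obs_interval = mean_obs_interval,
                 gap_schedule = gap_schedule,
                 class_mix = class_mix[ARGOS_CLASSES],
                 gamma_transit = gamma_transit, gamma_ars = gamma_ars,
                 Sigma = Sigma, switch_prob = switch_prob,
                 error_model = error_model, seed = as.integer(seed)),
            class = "sim_config")
}
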