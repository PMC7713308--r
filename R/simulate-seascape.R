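#' Simulate a synthetic seascape field set
#'
#' Generates smooth random fields (sums of low-frequency random Fourier
#' modes) for the standard covariate suite: SST and its spatial variability,
#' sea surface height anomaly and its variability, chlorophyll a, depth and
#' derived bathymetry (rugosity, slope, aspect), wind speed/direction, eddy
#' kinetic energy and an upwelling index. The fields are statistical
#' stand-ins with plausible magnitudes and spatial scales, not ocean physics.
#'
#' When `link` is supplied (the truth component of [simulate_tracks()]), SST
#' is warped so that cells visited while in ARS are pulled toward the middle
#' of `band` (default 14-17 degC), giving a positive-control habitat in which
#' ARS genuinely co-occurs with a known SST range while transit locations
#' fall across the wider SST field.
#'
#' @param bbox numeric `c(lon_min, lon_max, lat_min, lat_max)`; must cover
#'   the simulated tracks.
#' @param t_range POSIXct length-2; the time axis spans it at `cadence_days`.
#' @param res grid resolution, degrees.
#' @param cadence_days time step of dynamic fields, days.
#' @param link optional `sim_truth` object used to warp SST.
#' @param band numeric length-2 SST band (degC) favoured at ARS locations.
#' @param constant optional named list of constant values; named variables
#'   become spatially and temporally constant fields (useful for tests).
#' @param vars which variables to generate (default: the full suite).
#' @param seed integer seed.
#' @return a [seascape_fields()] object.
#' @export
simulate_seascape <- function(bbox, t_range, res = 0.25, cadence_days = 1,
                              link = NULL, band = c(14, 17),
                              constant = NULL, vars = NULL, seed = 1L) {
  stopifnot(length(bbox) == 4, bbox[2] > bbox[1], bbox[4] > bbox[3])
  set.seed(as.integer(seed))
  lon <- seq(bbox[1] + res / 2, bbox[2], by = res)
  lat <- seq(bbox[3] + res / 2, bbox[4], by = res)
  t_range <- .as_utc(t_range)
  time <- seq(t_range[1], t_range[2], by = cadence_days * 86400)
  nl <- length(lon); na <- length(lat); nt <- length(time)
  G <- expand.grid(lon = lon, lat = lat, KEEP.OUT.ATTRS = FALSE)
  tnum <- as.numeric(time - time[1]) / 86400

  ## smooth random field in [-1, 1]-ish: K random Fourier modes
  smooth_field <- function(dynamic = TRUE, lscale = 3, tscale = 30, K = 8) {
    a <- stats::rnorm(K); ph <- stats::runif(K, 0, 2 * pi)
    u <- matrix(stats::rnorm(2 * K, sd = 1 / lscale), K, 2)
    w <- if (dynamic) stats::rnorm(K, sd = 1 / tscale) else rep(0, K)
    f <- array(0, c(nl, na, if (dynamic) nt else 1L))
    for (k in seq_len(K)) {
      sp <- cos(2 * pi * (G$lon * u[k, 1] + G$lat * u[k, 2]) + ph[k])
      if (dynamic) {
        for (s in seq_len(nt))
          f[, , s] <- f[, , s] + a[k] * sp * cos(2 * pi * w[k] * tnum[s] + ph[k] / 2)
      } else f[, , 1] <- f[, , 1] + a[k] * sp
    }
    f / sqrt(sum(a^2) / 2 + 1e-12)
  }

  gens <- list(
    SST       = function() 16 + 3.2 * smooth_field(TRUE, lscale = 4, tscale = 45),
    SST_SD    = function() 0.6 + 0.45 * smooth_field(TRUE, lscale = 3)^2,
    SSHa      = function() 0.08 * smooth_field(TRUE, lscale = 3, tscale = 20),
    SSHa_SD   = function() 0.05 + 0.04 * smooth_field(TRUE, lscale = 2)^2,
    Chla      = function() exp(-1.2 + 0.9 * smooth_field(TRUE, lscale = 3, tscale = 25)),
    depth     = function() -(120 + 900 * smooth_field(FALSE, lscale = 5)^2),  # negative down
    rugosity  = function() 25 + 20 * smooth_field(FALSE, lscale = 2)^2,
    slope     = function() 1.5 + 1.2 * smooth_field(FALSE, lscale = 2)^2,
    aspect    = function() (180 + 180 * smooth_field(FALSE, lscale = 2)) %% 360,
    wind_speed = function() pmax(14 + 6 * smooth_field(TRUE, lscale = 6, tscale = 7), 0.5),
    wind_dir  = function() (200 + 120 * smooth_field(TRUE, lscale = 6, tscale = 7)) %% 360,
    EKE       = function() 0.02 + 0.015 * smooth_field(TRUE, lscale = 2)^2,
    upwelling = function() 8 * smooth_field(TRUE, lscale = 5, tscale = 10))
  if (is.null(vars)) vars <- names(gens)
  stopifnot(all(vars %in% names(gens)))
  data <- lapply(gens[vars], function(f) f())

  if (!is.null(link) && "SST" %in% vars) {
    stopifnot(inherits(link, "sim_truth"))
    mid <- mean(band)
    ## ARS visitation density on the grid (Gaussian kernel), normalised to [0,1]
    dens <- matrix(0, nl, na)
    bw <- 0.6
    for (wh in link$whales) {
      sel <- wh$b == 2L
      if (!any(sel)) next
      for (i in which(sel)) {
        dl <- (lon - wh$lon[i]) / bw
        da <- (lat - wh$lat[i]) / bw
        dens <- dens + exp(-0.5 * dl^2) %o% exp(-0.5 * da^2)
      }
    }
    if (max(dens) > 0) {
      m <- dens / max(dens)
      m <- m / (m + 0.08)  # saturate: visited cores -> ~1
      for (s in seq_len(dim(data$SST)[3]))
        data$SST[, , s] <- (1 - m) * data$SST[, , s] + m * mid
    }
  }

  if (!is.null(constant))
    for (v in names(constant)) {
      dynamic <- !is.null(data[[v]]) && dim(data[[v]])[3] > 1
      data[[v]] <- array(constant[[v]], c(nl, na, if (dynamic) nt else 1L))
    }

  seascape_fields(lon, lat, time, data,
                  units = c(SST = "degC", SST_SD = "degC", SSHa = "m", SSHa_SD = "m",
                            Chla = "mg m-3", depth = "m", wind_speed = "km h-1",
                            wind_dir = "deg", aspect = "deg"))
}
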