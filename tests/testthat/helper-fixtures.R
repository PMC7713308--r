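# shared fixture builders; everything is generated in code at test time

# a small synthetic track set with known truth
quick_sim <- function(n_whales = 2, n_steps = 200, seed = 42, ...) {
  simulate_tracks(sim_config(n_whales = n_whales, n_steps = n_steps,
                             seed = seed, ...))
}

# regular observation times: n fixes every `step` hours for one tag
regular_obs <- function(n, step_h = 2, t0 = as.POSIXct("2015-02-01", tz = "UTC"),
                        tag = "w1", lon = 140, lat = -38) {
  data.frame(tag_id = tag,
             time = t0 + (seq_len(n) - 1) * step_h * 3600,
             lc = "1", lon = lon + seq_len(n) * 0.01, lat = lat,
             stringsAsFactors = FALSE)
}

# independent linear-scan segmentation oracle: O(n) pass splitting on gaps
# strictly greater than gap_hours, then dropping short runs
segment_oracle <- function(times_h, gap_hours = 48, min_obs = 20) {
  if (length(times_h) == 0) return(list())
  times_h <- sort(times_h)
  segs <- list(); cur <- times_h[1]
  for (i in seq_along(times_h)[-1]) {
    if (times_h[i] - times_h[i - 1] > gap_hours) {
      segs[[length(segs) + 1]] <- cur
      cur <- numeric(0)
    }
    cur <- c(cur, times_h[i])
  }
  segs[[length(segs) + 1]] <- cur
  Filter(function(s) length(s) >= min_obs, segs)
}

# constant-field seascape over a bbox (all variables equal `value`)
constant_fields <- function(value = 15, bbox = c(135, 145, -42, -34),
                            vars = c("SST", "Chla", "depth"),
                            t_range = as.POSIXct(c("2015-01-01", "2015-06-01"),
                                                 tz = "UTC"),
                            res = 0.5) {
  lon <- seq(bbox[1] + res / 2, bbox[2], by = res)
  lat <- seq(bbox[3] + res / 2, bbox[4], by = res)
  time <- seq(t_range[1], t_range[2], by = 86400 * 5)
  data <- lapply(vars, function(v)
    array(value, c(length(lon), length(lat), length(time))))
  names(data) <- vars
  seascape_fields(lon, lat, time, data)
}

# state series laid out by hand for occupancy / region tests
toy_series <- function(lon, lat, t0 = as.POSIXct("2015-02-01", tz = "UTC"),
                       step_h = 3, tag = "w1") {
  data.frame(tag_id = tag, timestamp = t0 + (seq_along(lon) - 1) * step_h * 3600,
             lon = lon, lat = lat, stringsAsFactors = FALSE)
}

# a minimal hssm-shaped object whose posterior draws are the simulation truth
# plus controllable location jitter and state flips: lets the imputation
# machinery be exercised with posteriors of known width, independent of MCMC
fake_hssm <- function(sim, loc_sd = 0.005, flip = 0.02, n_draws = 40,
                      n_chains = 2, seed = 1) {
  set.seed(seed)
  whales <- sim$truth$whales
  segs <- lapply(whales, function(w) {
    Tn <- length(w$lon)
    list(lon = matrix(rep(w$lon, each = n_draws) +
                        rnorm(n_draws * Tn, 0, loc_sd), n_draws, Tn),
         lat = matrix(rep(w$lat, each = n_draws) +
                        rnorm(n_draws * Tn, 0, loc_sd), n_draws, Tn),
         b = matrix(ifelse(runif(n_draws * Tn) < flip,
                           3L - rep(w$b, each = n_draws),
                           rep(w$b, each = n_draws)), n_draws, Tn))
  })
  series <- lapply(whales, function(w) {
    out <- data.frame(time = w$time, lon = w$lon, lat = w$lat,
                      mean_b = w$b, p_ars = w$b - 1,
                      mode_state = w$b)
    attr(out, "tag_id") <- w$tag_id
    attr(out, "segment") <- 0L
    out
  })
  structure(list(series = series,
                 draws = list(segments = segs,
                              chain = rep(seq_len(n_chains),
                                          each = n_draws / n_chains),
                              draw = seq_len(n_draws)),
                 params = data.frame(idx = seq_len(n_draws))),
            class = "hssm")
}
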