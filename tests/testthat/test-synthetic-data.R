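# the track generator is the ground-truth source for every downstream stage

test_that("config validation enforces the documented invariants", {
  expect_error(sim_config(gamma_transit = 0.2, gamma_ars = 0.8), "gamma")
  expect_error(sim_config(gamma_transit = 1.2), "gamma")
  expect_error(sim_config(n_steps = 2), "n_steps")
  expect_error(sim_config(switch_prob = matrix(c(0.5, 0.4, 0.1, 0.9), 2, 2)),
               "sum to 1")
  expect_error(sim_config(Sigma = matrix(c(1, 2, 2, 1), 2, 2)),
               "positive definite")
  expect_error(sim_config(class_mix = c("3" = 1)), "class_mix|ARGOS")
})

test_that("simulation is bit-reproducible under a fixed seed", {
  a <- quick_sim(seed = 9)
  b <- quick_sim(seed = 9)
  expect_identical(a$observations, b$observations)
  expect_identical(a$truth$whales[[1]]$b, b$truth$whales[[1]]$b)
  c <- quick_sim(seed = 10)
  expect_false(identical(a$observations$lon, c$observations$lon))
})

test_that("zero-noise, equal-persistence limit puts fixes on the interpolated path", {
  em <- argos_error_model(scale_lon = setNames(rep(1e-12, 7), ARGOS_CLASSES),
                          scale_lat = setNames(rep(1e-12, 7), ARGOS_CLASSES),
                          df = setNames(rep(50, 7), ARGOS_CLASSES))
  # gamma_ars just below gamma_transit: states become indistinguishable
  cfg <- sim_config(n_whales = 1, n_steps = 100, error_model = em,
                    gamma_transit = 0.5, gamma_ars = 0.4999999, seed = 3)
  sim <- simulate_tracks(cfg)
  tr <- sim$truth$whales[[1]]
  ob <- sim$observations
  th <- as.numeric(difftime(ob$time, tr$time[1], units = "hours")) / cfg$dt
  k <- pmin(floor(th) + 1, length(tr$lon) - 1)
  j <- th - (k - 1)
  expect_equal(ob$lon, (1 - j) * tr$lon[k] + j * tr$lon[k + 1], tolerance = 1e-6)
  expect_equal(ob$lat, (1 - j) * tr$lat[k] + j * tr$lat[k + 1], tolerance = 1e-6)
})

test_that("an absorbing transition matrix freezes the behavioural state", {
  cfg <- sim_config(n_whales = 3, n_steps = 150, seed = 8,
                    switch_prob = matrix(c(1, 0, 0, 1), 2, 2))
  sim <- simulate_tracks(cfg)
  for (w in sim$truth$whales) expect_length(unique(w$b), 1L)
})

test_that("step-vector autocorrelation is higher inside transit runs than ARS runs", {
  cfg <- sim_config(n_whales = 1, n_steps = 2000, seed = 1)
  sim <- simulate_tracks(cfg)
  w <- sim$truth$whales[[1]]
  d <- cbind(diff(w$lon), diff(w$lat))
  b_step <- w$b[-1]
  lag1 <- function(sel) {
    # correlation of consecutive step vectors where both lie in the state
    i <- which(sel[-length(sel)] & sel[-1])
    stats::cor(c(d[i, ]), c(d[i + 1, ]))
  }
  r_transit <- lag1(b_step == 1)
  r_ars <- lag1(b_step == 2)
  expect_gt(r_transit, r_ars)
  expect_gt(r_transit, 0.5)
  expect_lt(r_ars, 0.5)
})

test_that("observed inter-fix intervals and class mix converge to the configuration", {
  cfg <- sim_config(n_whales = 6, n_steps = 1500, seed = 5)
  sim <- simulate_tracks(cfg)
  expect_gt(nrow(sim$observations), 1e4)
  ivs <- unlist(lapply(split(sim$observations, sim$observations$tag_id),
                       function(o) diff(as.numeric(o$time)) / 3600))
  expect_lt(abs(mean(ivs) - 2.3) / 2.3, 0.05)
  tab <- table(factor(sim$observations$lc, levels = ARGOS_CLASSES))
  p <- stats::chisq.test(tab, p = cfg$class_mix)$p.value
  expect_gt(p, 0.01)
})

test_that("scheduled gaps silence transmissions deterministically", {
  gaps <- list(cbind(100, 60))  # 60-h gap starting 100 h after deployment
  cfg <- sim_config(n_whales = 1, n_steps = 200, seed = 2, gap_schedule = gaps)
  sim <- simulate_tracks(cfg)
  rel_h <- as.numeric(difftime(sim$observations$time,
                               min(sim$observations$time), units = "hours"))
  t0 <- as.numeric(difftime(sim$observations$time[1],
                            sim$truth$whales[[1]]$time[1], units = "hours"))
  abs_h <- rel_h + t0
  expect_false(any(abs_h >= 100 & abs_h <= 160))
})

test_that("unlinked seascape SST is uncorrelated with the behavioural state", {
  # a single smooth field sampled along a spatially clustered track has few
  # effective degrees of freedom, so the state-SST correlation is averaged
  # over independent unlinked field draws; with no built-in link it centres
  # on zero
  sim <- quick_sim(n_whales = 3, n_steps = 700, seed = 21)
  rows <- do.call(rbind, lapply(sim$truth$whales, function(w)
    data.frame(tag_id = w$tag_id, time = w$time, lon = w$lon, lat = w$lat, b = w$b)))
  rows <- rows[seq_len(min(2000, nrow(rows))), ]
  cors <- vapply(1:20, function(i) {
    fs <- simulate_seascape(c(130, 150, -45, -30),
                            t_range = range(sim$observations$time),
                            link = NULL, vars = "SST", seed = 770 + i)
    cm <- extract_covariates(rows, fs, vars = "SST", transforms = NULL)
    ok <- !is.na(cm$SST)
    stats::cor(cm$SST[ok], rows$b[ok])
  }, 0)
  expect_lt(abs(mean(cors)), 0.1)
})

test_that("constant-field option returns the constant everywhere", {
  fs <- constant_fields(value = 15)
  sr <- toy_series(lon = c(137, 140, 143), lat = c(-40, -38, -36))
  cm <- extract_covariates(sr, fs, vars = "SST", transforms = NULL)
  expect_equal(cm$SST, rep(15, 3))
})

test_that("linked SST concentrates ARS locations inside the band", {
  sim <- quick_sim(n_whales = 3, n_steps = 700, seed = 31)
  fs <- simulate_seascape(c(130, 150, -45, -30),
                          t_range = range(sim$observations$time),
                          link = sim$truth, band = c(14, 17), seed = 78)
  rows <- do.call(rbind, lapply(sim$truth$whales, function(w)
    data.frame(tag_id = w$tag_id, time = w$time, lon = w$lon, lat = w$lat, b = w$b)))
  cm <- extract_covariates(rows, fs, vars = "SST", transforms = NULL)
  ok <- !is.na(cm$SST)
  in_band <- cm$SST >= 14 & cm$SST <= 17
  frac_ars <- mean(in_band[ok & rows$b == 2])
  frac_transit <- mean(in_band[ok & rows$b == 1])
  expect_gt(frac_ars, frac_transit)
})

test_that("field sets round-trip through long-format text", {
  fs <- simulate_seascape(c(138, 141, -40, -37), res = 0.5,
                          t_range = as.POSIXct(c("2015-02-01", "2015-02-10"),
                                               tz = "UTC"),
                          cadence_days = 3, seed = 4)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_fields(fs, path)
  back <- read_fields(path)
  expect_equal(back$lon, fs$lon)
  expect_equal(sort(names(back$data)), sort(names(fs$data)))
  expect_equal(back$data$SST, fs$data$SST, tolerance = 1e-6)
})
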