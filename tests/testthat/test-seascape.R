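# covariate extraction with lags, windows, transforms; collinearity screen

make_step_fields <- function(switch_time, before = 1, after = 0,
                             bbox = c(135, 145, -42, -34), res = 0.5) {
  # Chla equal to `before` until switch_time, `after` afterwards
  lon <- seq(bbox[1] + res / 2, bbox[2], by = res)
  lat <- seq(bbox[3] + res / 2, bbox[4], by = res)
  time <- seq(as.POSIXct("2015-01-01", tz = "UTC"),
              as.POSIXct("2015-04-01", tz = "UTC"), by = 86400)
  vals <- ifelse(time <= switch_time, before, after)
  a <- array(rep(vals, each = length(lon) * length(lat)),
             c(length(lon), length(lat), length(time)))
  seascape_fields(lon, lat, time, list(Chla = a))
}

test_that("lagged extraction equals a windowed-mean oracle on a step field", {
  sw <- as.POSIXct("2015-02-15", tz = "UTC")
  fs <- make_step_fields(sw)
  # locations at varying overlap with the pre-switch epoch
  when <- sw + c(-5, 5, 15, 29, 40) * 86400
  sr <- data.frame(tag_id = "w", time = when, lon = 140, lat = -38)
  cm <- extract_covariates(sr, fs, vars = "Chla", lags = list(Chla = 30),
                           transforms = NULL)
  oracle <- sapply(when, function(t1) {
    tt <- fs$time[fs$time >= t1 - 30 * 86400 & fs$time <= t1]
    mean(ifelse(tt <= sw, 1, 0))
  })
  expect_equal(cm$Chla, oracle, tolerance = 1e-12)
  expect_equal(cm$Chla[1], 1)      # fully before the switch
  expect_lt(cm$Chla[3], 1)         # partial overlap, proportional
  expect_gt(cm$Chla[3], 0)
  expect_equal(cm$Chla[5], 0)      # window fully after
})

test_that("a lag window preceding the raster start yields a counted missing row", {
  fs <- make_step_fields(as.POSIXct("2015-02-15", tz = "UTC"))
  sr <- data.frame(tag_id = "w",
                   time = as.POSIXct(c("2015-01-05", "2015-03-01"), tz = "UTC"),
                   lon = 140, lat = -38)
  cm <- extract_covariates(sr, fs, vars = "Chla", lags = list(Chla = 30),
                           transforms = NULL)
  expect_true(is.na(cm$Chla[1]))
  expect_false(is.na(cm$Chla[2]))
  expect_equal(attr(cm, "n_missing"), 1)
})

test_that("locations outside the raster yield counted missing rows", {
  fs <- constant_fields(15)
  sr <- data.frame(tag_id = "w",
                   time = as.POSIXct("2015-02-01", tz = "UTC") + c(0, 3600),
                   lon = c(140, 170), lat = c(-38, -38))
  cm <- extract_covariates(sr, fs, vars = "SST", transforms = NULL)
  expect_equal(cm$SST[1], 15)
  expect_true(is.na(cm$SST[2]))
  expect_equal(attr(cm, "n_missing"), 1)
})

test_that("point-location sampling ignores the whale's own position", {
  fs <- simulate_seascape(c(135, 145, -42, -34), res = 0.5,
                          t_range = as.POSIXct(c("2015-02-01", "2015-02-20"),
                                               tz = "UTC"), seed = 12)
  sr <- data.frame(tag_id = "w",
                   time = as.POSIXct("2015-02-10", tz = "UTC") + (0:9) * 3600,
                   lon = seq(136, 144, length.out = 10), lat = rep(-38, 10))
  cm <- extract_covariates(sr, fs, vars = "wind_speed", lags = list(),
                           at_point = list(wind_speed = c(140, -38)),
                           transforms = NULL)
  expect_equal(length(unique(cm$wind_speed)), 1L)
})

test_that("spatial-SD derivation is zero on a uniform field and positive otherwise", {
  fs <- constant_fields(15, res = 0.05)
  fs2 <- derive_sd(fs, "SST", area_km2 = 100)
  expect_true(all(fs2$data$SST_SD == 0))
  fs3 <- simulate_seascape(c(138, 140, -40, -38), res = 0.05,
                           t_range = as.POSIXct(c("2015-02-01", "2015-02-02"),
                                                tz = "UTC"), seed = 3)
  fs3 <- derive_sd(fs3, "SST", area_km2 = 100)
  expect_gt(max(fs3$data$SST_SD, na.rm = TRUE), 0)
})

test_that("declared transforms are applied once and recorded", {
  fs <- constant_fields(100, vars = c("Chla", "depth"))
  fs$data$depth <- fs$data$depth * -1  # depth stored negative-down: -100 m
  sr <- toy_series(lon = c(140, 141), lat = c(-38, -38))
  cm <- extract_covariates(sr, fs, vars = c("Chla", "depth"),
                           lags = list())
  expect_equal(cm$Chla, rep(log(100), 2))
  expect_equal(cm$depth, rep(log(100), 2))
  expect_equal(attr(cm, "meta")$transforms[["Chla"]], "log")
})

test_that("extraction is deterministic and lag commutes with time shifting", {
  fs <- simulate_seascape(c(135, 145, -42, -34), res = 0.5,
                          t_range = as.POSIXct(c("2015-01-01", "2015-04-01"),
                                               tz = "UTC"), seed = 6)
  sr <- data.frame(tag_id = "w",
                   time = as.POSIXct("2015-02-15", tz = "UTC") + (0:19) * 10800,
                   lon = seq(137, 143, length.out = 20), lat = rep(-38, 20))
  a <- extract_covariates(sr, fs, vars = "Chla", lags = list(Chla = 14),
                          transforms = NULL)
  b <- extract_covariates(sr, fs, vars = "Chla", lags = list(Chla = 14),
                          transforms = NULL)
  expect_identical(a$Chla, b$Chla)
  # shift both the field's clock and the series by the same offset
  shift <- 7 * 86400
  fs2 <- fs; fs2$time <- fs$time + shift
  sr2 <- sr; sr2$time <- sr$time + shift
  c2 <- extract_covariates(sr2, fs2, vars = "Chla", lags = list(Chla = 14),
                           transforms = NULL)
  expect_equal(c2$Chla, a$Chla, tolerance = 1e-12)
})

test_that("a duplicated column is flagged at rho = 1 and one copy dropped", {
  set.seed(10)
  m <- data.frame(SST = rnorm(100), depth = rnorm(100))
  m$SST_copy <- m$SST
  rep <- screen_collinearity(m)
  expect_equal(nrow(rep$dropped), 1)
  expect_true(rep$dropped$variable %in% c("SST", "SST_copy"))
  expect_equal(max(abs(rep$flagged_pairs$rho)), 1)
})

test_that("orthogonal simulated columns pass the screen with VIF near 1", {
  set.seed(1000)
  n <- 1000
  m <- as.data.frame(matrix(rnorm(n * 5), n, 5,
                            dimnames = list(NULL, c("SST", "SSHa", "depth",
                                                    "wind_speed", "Chla"))))
  rep <- screen_collinearity(m)
  expect_equal(nrow(rep$dropped), 0)
  expect_length(rep$high_vif, 0)
  expect_true(all(abs(rep$rho[upper.tri(rep$rho)]) < 0.1))
  expect_true(all(abs(rep$vif - 1) < 0.1))
})

test_that("collinear scale variants resolve to the longer scale (30-day, 100 km2)", {
  set.seed(20)
  base <- rnorm(300)
  m <- data.frame(Chla_14 = base + rnorm(300, 0, 0.1),
                  Chla_30 = base + rnorm(300, 0, 0.1),
                  SST_SD_50 = NA, SST_SD_100 = NA, depth = rnorm(300))
  b2 <- rnorm(300)
  m$SST_SD_50 <- b2 + rnorm(300, 0, 0.1)
  m$SST_SD_100 <- b2 + rnorm(300, 0, 0.1)
  rep <- screen_collinearity(m)
  expect_true("Chla_14" %in% rep$dropped$variable)
  expect_true("SST_SD_50" %in% rep$dropped$variable)
  expect_true(all(c("Chla_30", "SST_SD_100", "depth") %in% rep$kept))
})

test_that("a constant column is flagged with undefined VIF", {
  m <- data.frame(SST = rnorm(50), flat = rep(3, 50))
  rep <- screen_collinearity(m)
  expect_identical(rep$constant, "flat")
  expect_true(is.na(rep$vif["flat"]))
})

test_that("VIF agrees with the car oracle on a correlated design", {
  skip_if_not_installed("car")
  set.seed(30)
  n <- 400
  x1 <- rnorm(n); x2 <- 0.7 * x1 + rnorm(n, 0, 0.7); x3 <- rnorm(n)
  y <- rnorm(n)
  m <- data.frame(a = x1, b = x2, c = x3)
  rep <- screen_collinearity(m)
  ref <- car::vif(lm(y ~ a + b + c, data = cbind(m, y = y)))
  expect_equal(unname(rep$vif[c("a", "b", "c")]), unname(ref), tolerance = 1e-6)
})
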