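# the switching state-space model: grid construction, bookkeeping, and
# estimation behaviour in limits with known answers

test_that("regular grid ties observations to flanking states with weights in [0,1)", {
  o <- regular_obs(61, step_h = 3)  # spans 180 h exactly
  g <- build_regular_grid(o, dt = 3)
  expect_equal(g$n, floor(180 / 3) + 1)  # 61
  expect_equal(g$k, 1:61)  # every fix lies exactly on a grid time
  expect_equal(g$j, rep(0, 61))
  # a fix exactly on a grid time has j = 0; a midpoint fix has j = 0.5
  o2 <- regular_obs(3, step_h = 4.5)  # fixes at 0, 4.5, 9 h
  g2 <- build_regular_grid(o2, dt = 3)
  expect_equal(g2$k, c(1L, 2L, 4L))
  expect_equal(g2$j, c(0, 0.5, 0))
  expect_true(all(g2$j >= 0 & g2$j < 1))
  expect_error(build_regular_grid(regular_obs(3, step_h = 1), dt = 3), "two time steps")
})

test_that("retained-draw bookkeeping matches n_chains * floor(post/thin) for any plan", {
  expect_equal(retained_draws(mcmc_plan()), 2000)  # 2 x 30000 / 30
  for (p in list(c(2, 30000, 30), c(1, 1000, 7), c(3, 999, 10), c(2, 30, 30))) {
    plan <- mcmc_plan(n_chains = p[1], burn_in = 10, post_burn_in = p[2], thin = p[3])
    expect_equal(retained_draws(plan), p[1] * (p[2] %/% p[3]))
  }
  expect_error(mcmc_plan(post_burn_in = 10, thin = 30))
})

test_that("prob_ars maps the posterior mean state to [0,1] and flags violations", {
  expect_equal(prob_ars(c(1, 1.5, 2)), c(0, 0.5, 1))
  expect_error(prob_ars(c(0.9)), "1, 2")
  expect_error(prob_ars(c(2.2)), "1, 2")
})

test_that("compiled process density matches the R reference implementation", {
  set.seed(6)
  x <- cbind(cumsum(rnorm(30, 0, 0.05)), cumsum(rnorm(30, 0, 0.05)))
  b <- sample(1:2, 30, replace = TRUE)
  Sigma <- matrix(c(2.5e-3, 4e-4, 4e-4, 1.8e-3), 2)
  Pinv <- solve(Sigma)
  ldet <- determinant(Sigma, logarithm = TRUE)$modulus[1]
  r_ref <- arstrack:::.proc_loglik(x, b, c(0.8, 0.2), Pinv, ldet)
  # recover the same quantity from the sweep's sufficient statistics route:
  # sum of log-densities implied by residuals
  D <- diff(x)
  e <- D[-1, ] - c(0.8, 0.2)[b[3:30]] * D[-nrow(D), ]
  q <- rowSums((e %*% Pinv) * e)
  expect_equal(r_ref, -log(2 * pi) - 0.5 * ldet - 0.5 * q)
})

test_that("an hssm fit returns coherent draws, series and export table", {
  sim <- quick_sim(n_whales = 1, n_steps = 150, seed = 17)
  segs <- segment_track(sim$observations)
  plan <- mcmc_plan(n_chains = 2, burn_in = 150, post_burn_in = 90, thin = 3,
                    seed = 3)
  fit <- fit_hssm(segs, model_spec(), plan)
  expect_s3_class(fit, "hssm")
  expect_equal(nrow(fit$params), retained_draws(plan))
  # gamma ordering constraint holds in every retained draw (no label switching)
  expect_true(all(fit$params$gamma_transit > fit$params$gamma_ars))
  # states are 1/2 and p_ars = mean_b - 1 on every series
  for (sr in fit$series) {
    expect_true(all(fit$draws$segments[[1]]$b %in% 1:2))
    expect_equal(sr$p_ars, sr$mean_b - 1)
    expect_true(all(sr$mode_state == ifelse(sr$mean_b > 1.5, 2, 1)))
  }
  df <- as.data.frame(fit)
  expect_named(df, c("tag_id", "segment", "timestamp", "lon", "lat",
                     "lon_lo", "lon_hi", "lat_lo", "lat_hi",
                     "mean_b", "p_ars", "mode_state"))
  # a posterior draw is a coherent joint sample
  pd <- posterior_draws(fit, 5)
  expect_equal(nrow(pd), nrow(df))
  expect_true(all(pd$b %in% 1:2))
  # summaries print without error
  expect_output(print(fit), "state-space")
  expect_output(print(summary(fit)), "gamma_transit")
})

test_that("with near-zero measurement noise the posterior path sits on the truth", {
  em <- argos_error_model(scale_lon = setNames(rep(1e-4, 7), ARGOS_CLASSES),
                          scale_lat = setNames(rep(1e-4, 7), ARGOS_CLASSES),
                          df = setNames(rep(30, 7), ARGOS_CLASSES))
  cfg <- sim_config(n_whales = 1, n_steps = 120, error_model = em, seed = 23,
                    switch_prob = matrix(c(1, 0, 0, 1), 2, 2))  # single state
  sim <- simulate_tracks(cfg)
  segs <- segment_track(sim$observations)
  fit <- fit_hssm(segs, model_spec(error_model = em),
                  mcmc_plan(n_chains = 1, burn_in = 400, post_burn_in = 200,
                            thin = 2, seed = 4))
  sr <- fit$series[[1]]
  tr <- sim$truth$whales[[1]]
  tlon <- approx(as.numeric(tr$time), tr$lon, xout = as.numeric(sr$time),
                 rule = 2)$y
  tlat <- approx(as.numeric(tr$time), tr$lat, xout = as.numeric(sr$time),
                 rule = 2)$y
  rmse <- sqrt(mean((sr$lon - tlon)^2 + (sr$lat - tlat)^2))
  expect_lt(rmse, 0.05)  # well under the process step scale
})

test_that("state decoding degrades when the persistence contrast shrinks", {
  acc_for <- function(g1, g2, seed) {
    cfg <- sim_config(n_whales = 1, n_steps = 400, seed = seed,
                      gamma_transit = g1, gamma_ars = g2)
    sim <- simulate_tracks(cfg)
    segs <- segment_track(sim$observations)
    fit <- fit_hssm(segs, model_spec(),
                    mcmc_plan(n_chains = 1, burn_in = 600, post_burn_in = 300,
                              thin = 3, seed = seed))
    sr <- fit$series[[1]]
    tr <- sim$truth$whales[[1]]
    idx <- sapply(as.numeric(sr$time), function(t)
      which.min(abs(as.numeric(tr$time) - t)))
    mean(sr$mode_state == tr$b[idx])
  }
  a_strong <- acc_for(0.8, 0.2, 91)
  a_weak <- acc_for(0.55, 0.45, 91)
  expect_gt(a_strong, a_weak)
})

test_that("posteriors agree with an independent JAGS implementation of the same model", {
  skip_if_not_installed("rjags")
  cfg <- sim_config(n_whales = 1, n_steps = 150, seed = 777,
                    switch_prob = matrix(c(0.98, 0.02, 0.02, 0.98), 2, 2,
                                         byrow = TRUE))
  sim <- simulate_tracks(cfg)
  em <- cfg$error_model
  w <- sim$truth$whales[[1]]
  set.seed(2)
  lc <- sample(names(cfg$class_mix), length(w$time), replace = TRUE,
               prob = cfg$class_mix)
  # observations on the step grid so both implementations share the exact model
  obs <- data.frame(tag_id = w$tag_id, time = w$time, lc = lc,
                    lon = w$lon + rt(length(lc), em$df[lc]) * em$scale_lon[lc],
                    lat = w$lat + rt(length(lc), em$df[lc]) * em$scale_lat[lc])
  fit <- fit_hssm(segment_track(obs), model_spec(),
                  mcmc_plan(n_chains = 2, burn_in = 2000, post_burn_in = 2000,
                            thin = 4, seed = 99))
  jm <- "
  model {
    g1 ~ dunif(0, 1)
    g2 ~ dunif(0, g1)
    Omega[1:2,1:2] ~ dwish(R[,], 4)
    Sigma[1:2,1:2] <- inverse(Omega[,])
    a1 ~ dbeta(1, 1); a2 ~ dbeta(1, 1)
    P[1,1] <- a1; P[1,2] <- 1 - a1; P[2,1] <- 1 - a2; P[2,2] <- a2
    pi1 <- (1 - a2) / ((1 - a1) + (1 - a2))
    init[1] <- pi1; init[2] <- 1 - pi1
    b[2] ~ dcat(init[])
    gam[1] <- g1; gam[2] <- g2
    for (t in 3:T) {
      b[t] ~ dcat(P[b[t-1], ])
      mu[t,1:2] <- x[t-1,1:2] + gam[b[t]] * (x[t-1,1:2] - x[t-2,1:2])
      x[t,1:2] ~ dmnorm(mu[t,1:2], Omega[,])
    }
    for (t in 1:2) { x[t,1:2] ~ dmnorm(y0[t,1:2], W0[,]) }
    for (i in 1:T) {
      y[i,1] ~ dt(x[i,1], tau1[i], df[i])
      y[i,2] ~ dt(x[i,2], tau2[i], df[i])
    }
  }"
  dat <- list(T = nrow(obs), y = cbind(obs$lon, obs$lat),
              tau1 = unname(1 / em$scale_lon[obs$lc]^2),
              tau2 = unname(1 / em$scale_lat[obs$lc]^2),
              df = unname(em$df[obs$lc]), R = diag(2) * 1e-4,
              W0 = diag(2) * 1e-2, y0 = cbind(obs$lon, obs$lat)[1:2, ])
  m <- rjags::jags.model(textConnection(jm), data = dat, n.chains = 2,
                         quiet = TRUE, n.adapt = 2000,
                         inits = list(x = cbind(obs$lon, obs$lat)))
  update(m, 4000, progress.bar = "none")
  sm <- rjags::coda.samples(m, c("g1", "g2", "Sigma"), n.iter = 4000, thin = 4,
                            progress.bar = "none")
  s <- as.matrix(sm)
  expect_equal(mean(fit$params$gamma_transit), mean(s[, "g1"]), tolerance = 0.05)
  expect_equal(mean(fit$params$gamma_ars), mean(s[, "g2"]), tolerance = 0.12)
  expect_equal(mean(fit$params$sigma_lon), mean(s[, "Sigma[1,1]"]),
               tolerance = 0.15)
})
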