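#' Model specification for the switching state-space model
#'
#' The process model is a two-state switching first-difference correlated
#' random walk on latent regular-interval positions \eqn{x_t}:
#' \deqn{x_t - x_{t-1} = \gamma_{b_t} (x_{t-1} - x_{t-2}) + \epsilon_t,
#'   \quad \epsilon_t \sim N(0, \Sigma),}
#' where the behavioural state \eqn{b_t} is 1 (transit) or 2 (ARS) and
#' follows a first-order Markov chain. Identifiability is enforced by the
#' ordering constraint `gamma_transit > gamma_ars` (transit is the more
#' persistent state). Each irregular Argos fix is tied to its flanking
#' regular states by a linear interpolation weight and observed through a
#' fixed class-specific heavy-tailed t error (see [argos_error_model()]).
#'
#' Priors: uniform on each gamma subject to the ordering constraint,
#' inverse-Wishart on `Sigma` (weak by default), independent Beta on the two
#' state-persistence probabilities. `Sigma` is shared between behavioural
#' states (the states differ in persistence, not innovation scale); this is
#' a modelling choice exposed here rather than hard-coded elsewhere.
#'
#' @param dt regular time step, hours (default 3).
#' @param error_model fixed per-class measurement model.
#' @param hierarchy logical; share (gamma, Sigma, switch probabilities)
#'   across all segments/whales with per-whale latent paths (default TRUE).
#'   With FALSE each segment is fitted separately.
#' @param gamma_init length-2 initial values (transit, ARS).
#' @param sigma_prior list `df` (inverse-Wishart degrees of freedom) and
#'   `scale` (2x2 scale matrix, degrees^2).
#' @param alpha_prior length-2 Beta prior shape parameters for the
#'   state-persistence probabilities.
#' @param proposal_sd initial random-walk proposal s.d. for latent positions,
#'   degrees; adapted during burn-in.
#' @return object of class `hssm_spec`.
#' @export
model_spec <- function(dt = 3, error_model = argos_error_model(),
                       hierarchy = TRUE,
                       gamma_init = c(0.7, 0.3),
                       sigma_prior = list(df = 4, scale = diag(2) * 1e-4),
                       alpha_prior = c(1, 1),
                       proposal_sd = 0.02) {
  stopifnot(dt > 0, inherits(error_model, "argos_error_model"),
            length(gamma_init) == 2, gamma_init[1] > gamma_init[2],
            all(gamma_init > 0), all(gamma_init < 1))
  structure(list(dt = dt, error_model = error_model, hierarchy = hierarchy,
                 gamma_init = gamma_init, sigma_prior = sigma_prior,
                 alpha_prior = alpha_prior, proposal_sd = proposal_sd),
            class = "hssm_spec")
}

#' MCMC sampling plan
#'
#' Bookkeeping follows the bsam-style regimen: per chain, `burn_in` sweeps
#' are discarded, then `post_burn_in` sweeps are run of which every `thin`-th
#' is retained, so the retained-draw count is
#' `n_chains * floor(post_burn_in / thin)`. The publication-scale default
#' (2 chains, 80,000 burn-in, 30,000 post-burn-in, thin 30) retains 2000
#' draws; tests and examples use much smaller plans, which is configuration,
#' not a different algorithm.
#'
#' @param n_chains number of chains (default 2).
#' @param burn_in discarded sweeps per chain (default 80000).
#' @param post_burn_in post-burn-in sweeps per chain (default 30000).
#' @param thin retain every `thin`-th sweep (default 30).
#' @param seed integer seed.
#' @return object of class `mcmc_plan`.
#' @examples
#' retained_draws(mcmc_plan())  # 2000
#' @export
mcmc_plan <- function(n_chains = 2, burn_in = 80000, post_burn_in = 30000,
                      thin = 30, seed = 1L) {
  stopifnot(n_chains >= 1, burn_in >= 0, post_burn_in >= thin, thin >= 1)
  structure(list(n_chains = as.integer(n_chains), burn_in = as.integer(burn_in),
                 post_burn_in = as.integer(post_burn_in), thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "mcmc_plan")
}

#' @rdname mcmc_plan
#' @param plan an `mcmc_plan`.
#' @export
retained_draws <- function(plan) plan$n_chains * (plan$post_burn_in %/% plan$thin)

#' Regular state grid and interpolation weights for a segment
#'
#' Lays a regular `dt`-hour grid over a segment's time range and ties each
#' observation i to its flanking regular states k and k+1 with weight
#' `j = (t_i - t_k)/dt` in [0, 1), so the measurement equation is
#' `y_i = (1-j) x_k + j x_{k+1} + error`. The grid has
#' `floor(span/dt) + 1` states, plus one more when the span is not an exact
#' multiple of `dt` (so trailing observations always have a flanking pair).
#'
#' @param segment a `track_segment` (or observation data.frame).
#' @param dt step in hours.
#' @return list `times` (POSIXct grid), `n`, and per observation `k`
#'   (1-based left state) and `j` (weight in [0,1)).
#' @export
build_regular_grid <- function(segment, dt = 3) {
  tt <- as.numeric(.as_utc(segment$time))
  stopifnot(!is.unsorted(tt))
  span <- (tt[length(tt)] - tt[1]) / 3600
  if (span < 2 * dt) stop("segment spans less than two time steps")
  n <- floor(span / dt) + 1L
  if (span > (n - 1) * dt + 1e-9) n <- n + 1L  # cover trailing observations
  t0 <- tt[1]
  frac <- (tt - t0) / 3600 / dt
  k <- pmin(floor(frac + 1e-9) + 1L, n)
  j <- pmax(frac - (k - 1L), 0)
  j[k == n] <- 0  # a fix on the final grid time is attributed to it alone
  times <- .as_utc(as.POSIXct(t0 + (seq_len(n) - 1) * dt * 3600,
                              origin = "1970-01-01", tz = "UTC"))
  list(times = times, n = n, k = as.integer(k), j = j)
}

## ---- internal sampler machinery ------------------------------------------

# per-time process log-density for t = 3..T given states b and parameters
.proc_loglik <- function(x, b, gamma, Pinv, ldet) {
  Tn <- nrow(x)
  D <- x[-1, , drop = FALSE] - x[-Tn, , drop = FALSE]      # displacements, T-1 rows
  g <- gamma[b[3:Tn]]
  e <- D[-1, , drop = FALSE] - g * D[-(Tn - 1), , drop = FALSE]
  q <- rowSums((e %*% Pinv) * e)
  -log(2 * pi) - 0.5 * ldet - 0.5 * q
}

# same but for a fixed state s in every slot (FFBS emissions)
.proc_loglik_state <- function(x, g, Pinv, ldet) {
  Tn <- nrow(x)
  D <- x[-1, , drop = FALSE] - x[-Tn, , drop = FALSE]
  e <- D[-1, , drop = FALSE] - g * D[-(Tn - 1), , drop = FALSE]
  q <- rowSums((e %*% Pinv) * e)
  -log(2 * pi) - 0.5 * ldet - 0.5 * q
}

.obs_loglik <- function(x, ob, em) {
  pred_lon <- (1 - ob$j) * x[ob$k, 1] + ob$j * x[ob$k2, 1]
  pred_lat <- (1 - ob$j) * x[ob$k, 2] + ob$j * x[ob$k2, 2]
  .argos_logdens(em, ob$lc, ob$lon - pred_lon, ob$lat - pred_lat)
}

# forward-filter backward-sample for the two-state chain
.ffbs <- function(E, logP, log_init) {
  Tn <- nrow(E)
  f <- matrix(-Inf, Tn, 2)
  f[1, ] <- log_init + E[1, ]
  for (t in 2:Tn) {
    a1 <- f[t - 1, 1] + logP[1, ]
    a2 <- f[t - 1, 2] + logP[2, ]
    m <- pmax(a1, a2)
    f[t, ] <- E[t, ] + m + log(exp(a1 - m) + exp(a2 - m))
  }
  b <- integer(Tn)
  p <- exp(f[Tn, ] - max(f[Tn, ]))
  b[Tn] <- if (stats::runif(1) < p[1] / sum(p)) 1L else 2L
  for (t in (Tn - 1):1) {
    lp <- f[t, ] + logP[, b[t + 1]]
    p <- exp(lp - max(lp))
    b[t] <- if (stats::runif(1) < p[1] / sum(p)) 1L else 2L
  }
  b
}

# per-site observation adjacency in CSR form (0-based, for the C++ sweep):
# observation i is affected by moves of either flanking state k or k+1
.obs_adjacency <- function(Tn, k0, k20) {
  site <- c(k0, k20[k20 != k0])
  obs <- c(seq_along(k0), which(k20 != k0)) - 1L
  ord <- order(site, obs)
  list(ptr = c(0L, cumsum(tabulate(site + 1L, nbins = Tn))),
       obs = obs[ord])
}

#' Fit the hierarchical switching state-space model
#'
#' Jointly estimates latent regular-interval locations and discrete
#' behavioural states for one or more track segments by Markov chain Monte
#' Carlo (Metropolis-within-Gibbs): latent positions are updated by a blocked
#' random-walk Metropolis step (exact, using a mod-3 colouring so blocked
#' sites are conditionally independent), states by a forward-filter
#' backward-sampling sweep, and the movement parameters (`gamma` pair,
#' `Sigma`, state-persistence probabilities) by conjugate Gibbs draws pooled
#' across segments when `hierarchy` is on. The gamma ordering constraint
#' (transit more persistent than ARS) is enforced in every draw, so the
#' reported states never label-switch.
#'
#' @param segments a `track_segment` or list of them (see [segment_track()]).
#' @param spec a [model_spec()].
#' @param plan an [mcmc_plan()].
#' @param verbose print progress.
#' @return an object of class `hssm`; see [summary.hssm()],
#'   [as.data.frame.hssm()], [prob_ars()], [posterior_draws()].
#' @export
fit_hssm <- function(segments, spec = model_spec(), plan = mcmc_plan(),
                     verbose = FALSE) {
  if (inherits(segments, "track_segment") || is.data.frame(segments))
    segments <- list(segments)
  stopifnot(length(segments) >= 1, inherits(spec, "hssm_spec"),
            inherits(plan, "mcmc_plan"))
  em <- spec$error_model
  nseg <- length(segments)

  ## per-segment fixed structures
  segdat <- lapply(segments, function(seg) {
    g <- build_regular_grid(seg, spec$dt)
    lc <- as.character(seg$lc)
    ob <- list(lon = seg$lon, lat = seg$lat, lc = lc,
               k = g$k, j = g$j, k2 = pmin(g$k + 1L, g$n),
               sc_lon = unname(em$scale_lon[lc]),
               sc_lat = unname(em$scale_lat[lc]),
               sc_df = unname(em$df[lc]))
    x0 <- cbind(stats::approx(as.numeric(.as_utc(seg$time)), seg$lon,
                              xout = as.numeric(g$times), rule = 2,
                              ties = mean)$y,
                stats::approx(as.numeric(.as_utc(seg$time)), seg$lat,
                              xout = as.numeric(g$times), rule = 2,
                              ties = mean)$y)
    list(grid = g, ob = ob, x0 = x0,
         adj = .obs_adjacency(g$n, ob$k - 1L, ob$k2 - 1L),
         tag_id = attr(seg, "tag_id") %||% seg$tag_id[1],
         segment = attr(seg, "segment") %||% 0L)
  })

  n_keep <- plan$post_burn_in %/% plan$thin
  total_keep <- plan$n_chains * n_keep
  npar <- 7L
  par_draws <- matrix(NA_real_, total_keep, npar,
                      dimnames = list(NULL, c("gamma_transit", "gamma_ars",
                                              "sigma_lon", "sigma_lat", "sigma_lonlat",
                                              "alpha_transit", "alpha_ars")))
  chain_id <- integer(total_keep)
  draw_id <- integer(total_keep)
  store <- lapply(segdat, function(sd) {
    Tn <- sd$grid$n
    list(lon = matrix(NA_real_, total_keep, Tn),
         lat = matrix(NA_real_, total_keep, Tn),
         b = matrix(NA_integer_, total_keep, Tn))
  })
  acc_rates <- numeric(0)
  row0 <- 0L

  for (ch in seq_len(plan$n_chains)) {
    set.seed(stage_seed(plan$seed, paste0("chain", ch)))
    ## initial values (chains start overdispersed in gamma)
    gamma <- pmin(pmax(spec$gamma_init + stats::rnorm(2, 0, 0.05), 0.02), 0.98)
    if (gamma[1] <= gamma[2]) gamma <- sort(gamma, decreasing = TRUE)
    alpha <- c(0.9, 0.9)
    X <- lapply(segdat, function(sd) sd$x0)
    B <- lapply(segdat, function(sd) {
      Tn <- sd$grid$n
      sp <- sqrt(rowSums((sd$x0[-1, , drop = FALSE] - sd$x0[-Tn, , drop = FALSE])^2))
      b <- c(1L, ifelse(sp > stats::median(sp), 1L, 2L))
      b
    })
    Dall <- do.call(rbind, lapply(X, function(x) diff(x)))
    Sigma <- stats::cov(diff(Dall)) / 2 + diag(2) * 1e-6
    ## per-site proposal scales, adapted in 25-sweep windows during burn-in
    tau <- lapply(segdat, function(sd) rep(spec$proposal_sd, sd$grid$n))
    acc_win <- lapply(segdat, function(sd) rep(0, sd$grid$n))
    racc <- rep(0.3, nseg)

    n_sweeps <- plan$burn_in + plan$post_burn_in
    kept <- 0L
    for (it in seq_len(n_sweeps)) {
      Pinv <- solve(Sigma)
      ldet <- determinant(Sigma, logarithm = TRUE)$modulus[1]

      ## one compiled sweep per segment: latent path Metropolis + state FFBS
      ## + sufficient statistics, pooled across segments
      A <- c(0, 0); M <- c(0, 0)
      SS <- matrix(0, 2, 2); nres <- 0L
      n_stay <- c(0, 0); n_leave <- c(0, 0)
      for (s in seq_len(nseg)) {
        ob <- segdat[[s]]$ob
        up <- .hssm_sweep(X[[s]][, 1], X[[s]][, 2], B[[s]],
                          ob$lon, ob$lat, ob$k - 1L, ob$k2 - 1L, ob$j,
                          ob$sc_lon, ob$sc_lat, ob$sc_df,
                          segdat[[s]]$adj$ptr, segdat[[s]]$adj$obs,
                          gamma[1], gamma[2],
                          Pinv[1, 1], Pinv[1, 2], Pinv[2, 2], ldet,
                          alpha[1], alpha[2], tau[[s]])
        X[[s]] <- cbind(up$lon, up$lat)
        B[[s]] <- up$b
        racc[s] <- 0.9 * racc[s] + 0.1 * up$rate
        if (it <= plan$burn_in) {
          acc_win[[s]] <- acc_win[[s]] + up$acc_site
          if (it %% 25 == 0) {
            tau[[s]] <- pmin(1, pmax(1e-4, tau[[s]] *
                                     exp(0.8 * (acc_win[[s]] / 25 - 0.3))))
            acc_win[[s]][] <- 0
          }
        }
        A <- A + up$A; M <- M + up$M
        SS <- SS + matrix(up$SS[c(1, 2, 2, 3)], 2, 2)
        nres <- nres + up$nres
        n_stay <- n_stay + up$nstay; n_leave <- n_leave + up$nleave
      }
      ## gamma: truncated-normal Gibbs under the ordering constraint
      if (A[1] > 0) gamma[1] <- .rtnorm(M[1] / A[1], 1 / sqrt(A[1]), gamma[2], 1)
      if (A[2] > 0) gamma[2] <- .rtnorm(M[2] / A[2], 1 / sqrt(A[2]), 0, gamma[1])
      ## Sigma: inverse-Wishart
      Sn <- spec$sigma_prior$scale + SS
      W <- stats::rWishart(1, spec$sigma_prior$df + nres, solve(Sn))[, , 1]
      Sigma <- solve(W)
      ## switch probabilities: Beta
      ap <- spec$alpha_prior
      alpha[1] <- stats::rbeta(1, ap[1] + n_stay[1], ap[2] + n_leave[1])
      alpha[2] <- stats::rbeta(1, ap[1] + n_stay[2], ap[2] + n_leave[2])

      ## retention
      if (it > plan$burn_in && (it - plan$burn_in) %% plan$thin == 0 && kept < n_keep) {
        kept <- kept + 1L
        r <- row0 + kept
        par_draws[r, ] <- c(gamma, Sigma[1, 1], Sigma[2, 2], Sigma[1, 2], alpha)
        chain_id[r] <- ch
        draw_id[r] <- kept
        for (s in seq_len(nseg)) {
          store[[s]]$lon[r, ] <- X[[s]][, 1]
          store[[s]]$lat[r, ] <- X[[s]][, 2]
          store[[s]]$b[r, ] <- B[[s]]
        }
      }
      if (verbose && it %% 500 == 0)
        message(sprintf("chain %d sweep %d/%d (acc %.2f)", ch, it, n_sweeps,
                        mean(racc)))
    }
    acc_rates <- c(acc_rates, mean(racc))
    row0 <- row0 + n_keep
  }

  ## posterior summaries per segment
  series <- lapply(seq_len(nseg), function(s) {
    st <- store[[s]]
    mean_b <- colMeans(st$b)
    qs <- function(m, p) apply(m, 2, stats::quantile, probs = p, names = FALSE)
    out <- data.frame(time = segdat[[s]]$grid$times,
                      lon = colMeans(st$lon), lat = colMeans(st$lat),
                      lon_lo = qs(st$lon, 0.025), lon_hi = qs(st$lon, 0.975),
                      lat_lo = qs(st$lat, 0.025), lat_hi = qs(st$lat, 0.975),
                      mean_b = mean_b, p_ars = mean_b - 1,
                      mode_state = ifelse(mean_b > 1.5, 2L, 1L))
    attr(out, "tag_id") <- segdat[[s]]$tag_id
    attr(out, "segment") <- segdat[[s]]$segment
    out
  })

  conv <- NULL
  if (plan$n_chains >= 2) {
    chains <- lapply(seq_len(plan$n_chains),
                     function(ch) par_draws[chain_id == ch, , drop = FALSE])
    conv <- diagnose(chains)
  }

  structure(list(series = series,
                 draws = list(segments = store, chain = chain_id, draw = draw_id),
                 params = data.frame(par_draws, chain = chain_id, draw = draw_id),
                 segments_meta = data.frame(
                   tag_id = vapply(segdat, `[[`, "", "tag_id"),
                   segment = vapply(segdat, function(z) as.integer(z$segment), 0L)),
                 spec = spec, plan = plan, convergence = conv,
                 accept_rate = acc_rates),
            class = "hssm")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
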