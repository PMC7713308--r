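#' Ancestry classification by pygmy-fraction thresholds
#'
#' Classifies an individual as a pure pygmy blue whale when at least 98% of
#' its estimated ancestry originates from the pygmy subspecies, as a pure
#' Antarctic blue whale when no more than 12% does, and as admixed
#' otherwise. Both boundaries are inclusive.
#'
#' @param pygmy_fraction numeric in [0, 1] (vectorised).
#' @return character vector: `"pure_pygmy"`, `"pure_antarctic"` or
#'   `"admixed"`.
#' @examples
#' classify_ancestry(c(0.981, 0.98, 0.5, 0.12))
#' @export
classify_ancestry <- function(pygmy_fraction) {
  if (any(is.na(pygmy_fraction)) || any(pygmy_fraction < 0 | pygmy_fraction > 1))
    stop("pygmy_fraction must lie in [0, 1]")
  ifelse(pygmy_fraction >= 0.98, "pure_pygmy",
         ifelse(pygmy_fraction <= 0.12, "pure_antarctic", "admixed"))
}

#' Per-whale summary table with aggregate statistics
#'
#' Binds per-whale metric rows and appends min/max/mean/SD aggregates of the
#' numeric columns. The SD convention is the sample SD (n - 1); the
#' population SD is reported alongside in the aggregate list for
#' completeness.
#'
#' @param metrics data.frame of per-whale rows (e.g. from [track_metrics()]
#'   or [pygmy_whale_summary()]).
#' @param cols numeric columns to aggregate; defaults to all numeric ones.
#' @return list `table` (the input), `aggregates` (data.frame with rows
#'   min/max/mean/sd/sd_pop per column).
#' @export
summary_table <- function(metrics, cols = NULL) {
  stopifnot(nrow(metrics) >= 1)
  if (is.null(cols)) cols <- names(metrics)[vapply(metrics, is.numeric, TRUE)]
  agg <- sapply(cols, function(cn) {
    v <- metrics[[cn]][!is.na(metrics[[cn]])]
    n <- length(v)
    c(min = min(v), max = max(v), mean = mean(v),
      sd = if (n > 1) stats::sd(v) else 0,
      sd_pop = sqrt(mean((v - mean(v))^2)))
  })
  list(table = metrics, aggregates = as.data.frame(agg))
}

#' Pipeline configuration
#'
#' Bundles every stage's parameters. All stochastic stages derive their
#' seeds from `seed` via [stage_seed()], so a rerun with the same
#' configuration is reproducible end to end.
#'
#' @param sim a [sim_config()] for synthetic input (or NULL when
#'   `observations_path` points at real data).
#' @param observations_path optional path to Argos-style delimited text.
#' @param fields a [seascape_fields()] object, or NULL to simulate one.
#' @param gap_hours,min_obs segmentation parameters.
#' @param spec a [model_spec()].
#' @param plan an [mcmc_plan()].
#' @param mask a [region_mask()] for the habitat stage.
#' @param gamm a [gamm_spec()] or NULL to skip the habitat stage.
#' @param n_imputations refits for [imputation_significance()].
#' @param cell_deg occupancy cell size.
#' @param out_dir output directory (created); NULL writes nothing.
#' @param seed global integer seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), observations_path = NULL,
                            fields = NULL, gap_hours = 48, min_obs = 20,
                            spec = model_spec(), plan = mcmc_plan(),
                            mask = region_mask("GSACUS"),
                            gamm = NULL, n_imputations = 100,
                            cell_deg = 0.5, out_dir = NULL, seed = 1L) {
  structure(list(sim = sim, observations_path = observations_path,
                 fields = fields, gap_hours = gap_hours, min_obs = min_obs,
                 spec = spec, plan = plan, mask = mask, gamm = gamm,
                 n_imputations = n_imputations, cell_deg = cell_deg,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Read (or simulate) observations, segment tracks, fit the switching
#' state-space model, derive track metrics and the weighted-day occupancy
#' grid, then — when a GAMM spec is configured — extract seascape
#' covariates, screen collinearity, fit the behaviour-seascape model and run
#' the multiple-imputation significance procedure. Artifacts and a run
#' manifest (parameter echo, seeds, stage timings) are written to
#' `config$out_dir` when set. Stage failures abort with the stage name;
#' outputs of completed stages are already on disk.
#'
#' @param config a [pipeline_config()].
#' @param verbose print stage progress.
#' @return a `pipeline_result` list: `observations, segments, fit, series,
#'   metrics, occupancy, covariates, screen, gamm, imputation, manifest`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  t_start <- Sys.time()
  manifest <- list(seed = config$seed,
                   started = format(t_start, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
                   stages = list())
  out <- list()
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    manifest$stages[[name]] <<- list(
      seconds = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2))
    say("stage %s done", name)
    res
  }
  if (!is.null(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  emit <- function(df, file) {
    if (!is.null(config$out_dir))
      utils::write.csv(df, file.path(config$out_dir, file), row.names = FALSE)
  }
  ## inputs are validated before any expensive fitting
  if (!is.null(config$observations_path) && !file.exists(config$observations_path))
    stop("observations_path does not exist: ", config$observations_path)
  if (is.null(config$observations_path) && is.null(config$sim))
    stop("neither observations_path nor a simulation is configured")
  if (!is.null(config$gamm) && is.null(config$fields) && is.null(config$sim))
    stop("habitat stage enabled but no seascape fields or simulation configured")

  truth <- NULL
  obs <- stage("read", {
    if (!is.null(config$observations_path)) {
      read_argos(config$observations_path)
    } else {
      cfg <- config$sim
      cfg$seed <- stage_seed(config$seed, "simulate")
      sim <- simulate_tracks(cfg)
      truth <- sim$truth
      sim$observations
    }
  })
  out$observations <- obs
  out$truth <- truth
  emit(data.frame(obs, stringsAsFactors = FALSE), "observations.csv")

  segments <- stage("segment", {
    segs <- unlist(lapply(split(obs, obs$tag_id), segment_track,
                          gap_hours = config$gap_hours, min_obs = config$min_obs),
                   recursive = FALSE)
    if (!length(segs)) stop("no segments survive the gap/length filters")
    segs
  })
  out$segments <- segments

  fit <- stage("fit_hssm", {
    plan <- config$plan
    plan$seed <- stage_seed(config$seed, "mcmc")
    fit_hssm(segments, config$spec, plan)
  })
  out$fit <- fit
  series <- as.data.frame(fit)
  out$series <- series
  emit(series, "state_series.csv")

  out$metrics <- stage("metrics", {
    mt <- do.call(rbind, lapply(split(series, series$tag_id), track_metrics,
                                dt_hours = config$spec$dt, mask = config$mask))
    rownames(mt) <- NULL
    mt
  })
  emit(out$metrics, "track_metrics.csv")

  out$occupancy <- stage("occupancy", {
    occupancy(series, cell_deg = config$cell_deg, dt_hours = config$spec$dt)
  })
  emit(as.data.frame(out$occupancy), "occupancy.csv")

  if (!is.null(config$gamm)) {
    fields <- config$fields
    if (is.null(fields)) {
      fields <- stage("simulate_seascape", {
        pad <- 1
        bbox <- c(min(series$lon) - pad, max(series$lon) + pad,
                  min(series$lat) - pad, max(series$lat) + pad)
        simulate_seascape(bbox,
                          t_range = range(series$timestamp) + c(-35, 1) * 86400,
                          link = truth,
                          seed = stage_seed(config$seed, "seascape"))
      })
    }
    out$fields <- fields
    out$covariates <- stage("extract", {
      sel <- config$mask(series$lon, series$lat)
      extract_covariates(series[sel, , drop = FALSE], fields,
                         vars = config$gamm$smooths)
    })
    out$screen <- stage("screen", screen_collinearity(out$covariates))
    gspec <- config$gamm
    gspec$smooths <- intersect(gspec$smooths, out$screen$kept)
    out$gamm <- stage("fit_gamm", fit_gamm(out$covariates, gspec))
    out$imputation <- stage("imputation", {
      imputation_significance(fit, fields, gspec,
                              n_iter = config$n_imputations, mask = config$mask,
                              seed = stage_seed(config$seed, "imputation"))
    })
    emit(out$imputation$counts, "imputation_significance.csv")
    emit(out$gamm$smooth_table, "gamm_smooths.csv")
  }

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  manifest$r_version <- R.version.string
  manifest$parameters <- list(gap_hours = config$gap_hours,
                              min_obs = config$min_obs, dt = config$spec$dt,
                              n_chains = config$plan$n_chains,
                              burn_in = config$plan$burn_in,
                              post_burn_in = config$plan$post_burn_in,
                              thin = config$plan$thin,
                              cell_deg = config$cell_deg,
                              n_imputations = config$n_imputations)
  manifest$converged <- is.null(fit$convergence) || fit$convergence$converged
  out$manifest <- manifest
  if (!is.null(config$out_dir))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  class(out) <- "pipeline_result"
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result:\n")
  cat(sprintf("  %d observations, %d segments, %d state locations\n",
              nrow(x$observations), length(x$segments), nrow(x$series)))
  if (!is.null(x$imputation)) print(x$imputation)
  invisible(x)
}
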