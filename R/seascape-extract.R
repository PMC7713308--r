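#' Derive a spatial-SD field from a parent field
#'
#' Adds `<var>_SD`, the standard deviation of `var` over the set of cells
#' whose centers fall within a square of the given area centered on each
#' cell — the standard "variability over ~100 km^2" covariate. With grids
#' coarser than the window the neighbourhood collapses to the cell itself
#' and the SD is 0.
#'
#' @param fields a [seascape_fields()] object.
#' @param var parent variable name.
#' @param area_km2 window area (square), km^2.
#' @return the field set with `<var>_SD` added/replaced.
#' @export
derive_sd <- function(fields, var, area_km2 = 100) {
  stopifnot(inherits(fields, "seascape_fields"), var %in% names(fields$data))
  a <- fields$data[[var]]
  res <- diff(fields$lon[1:2])
  half <- sqrt(area_km2) / 2
  nl <- length(fields$lon); na <- length(fields$lat); nt <- dim(a)[3]
  out <- array(NA_real_, dim(a))
  km_lat <- 111.195
  hw_lat <- max(0L, floor(half / (km_lat * res)))
  for (jj in seq_len(na)) {
    km_lon <- km_lat * cos(fields$lat[jj] * pi / 180)
    hw_lon <- max(0L, floor(half / (km_lon * res)))
    j0 <- max(1, jj - hw_lat); j1 <- min(na, jj + hw_lat)
    for (ii in seq_len(nl)) {
      i0 <- max(1, ii - hw_lon); i1 <- min(nl, ii + hw_lon)
      for (ss in seq_len(nt)) {
        block <- a[i0:i1, j0:j1, ss]
        out[ii, jj, ss] <- if (length(block) > 1) stats::sd(block) else 0
      }
    }
  }
  fields$data[[paste0(var, "_SD")]] <- out
  fields
}

# nearest-cell indices; NA outside the grid (beyond half a cell of the edge)
.cell_index <- function(coord, axis) {
  res <- diff(axis[1:2])
  i <- round((coord - axis[1]) / res) + 1
  i[coord < axis[1] - res / 2 | coord > axis[length(axis)] + res / 2] <- NA
  as.integer(pmin(pmax(i, 1), length(axis)))
}

.time_index <- function(tq, taxis) {
  if (length(taxis) == 1) return(rep(1L, length(tq)))
  i <- findInterval(as.numeric(tq), as.numeric(taxis), all.inside = FALSE)
  i[i < 1] <- NA
  nt <- length(taxis)
  ## snap to nearest slice
  i2 <- pmin(i + 1L, nt)
  near <- ifelse(!is.na(i) &
                   abs(as.numeric(tq) - as.numeric(taxis)[pmax(i, 1)]) <=
                   abs(as.numeric(tq) - as.numeric(taxis)[i2]),
                 i, i2)
  near[as.numeric(tq) > as.numeric(taxis[nt]) + diff(as.numeric(taxis[1:2]))] <- NA
  as.integer(near)
}

#' Extract seascape covariates at state locations
#'
#' Samples each variable at the nearest cell and time slice of each location.
#' Variables listed in `lags` are instead averaged over the window of
#' `lag_days` days ending at the location's timestamp (the "n-day prior
#' average"); variables listed in `at_point` are sampled at a fixed nominated
#' coordinate rather than at the whale (as for the wind series). Transforms
#' (`"log"`, `"log10"`, `"log_abs"`) are applied here, once, and recorded in
#' the metadata so the habitat model sees final covariates. Locations outside
#' the raster (or with lag windows preceding the raster start) yield `NA`
#' rows, which are counted, not silently dropped.
#'
#' @param series state-series data.frame (`tag_id, lon, lat`, time column,
#'   optionally `mode_state`).
#' @param fields a [seascape_fields()] object.
#' @param vars variables to extract (default: all in `fields`).
#' @param lags named list of lag windows in days, e.g. `list(Chla = 30,
#'   wind_speed = 7)`.
#' @param at_point named list of `c(lon, lat)` fixed sampling coordinates.
#' @param transforms named character vector of transforms.
#' @return data.frame with `tag_id`, time, `mode_state` (if present) and one
#'   column per variable; attributes `n_missing`, `meta`.
#' @export
extract_covariates <- function(series, fields, vars = names(fields$data),
                               lags = list(Chla = 30, wind_speed = 7),
                               at_point = NULL,
                               transforms = c(Chla = "log", SSHa_SD = "log10",
                                              depth = "log_abs")) {
  stopifnot(inherits(fields, "seascape_fields"))
  tcol <- if ("timestamp" %in% names(series)) "timestamp" else "time"
  tq <- .as_utc(series[[tcol]])
  n <- nrow(series)
  ii <- .cell_index(series$lon, fields$lon)
  jj <- .cell_index(series$lat, fields$lat)
  ti <- .time_index(tq, fields$time)

  out <- data.frame(tag_id = series$tag_id %||% rep(NA_character_, n), time = tq)
  if ("mode_state" %in% names(series)) out$mode_state <- series$mode_state

  tnum <- as.numeric(fields$time)
  for (v in vars) {
    a <- fields$data[[v]]
    if (is.null(a)) stop("unknown field: ", v)
    static <- dim(a)[3] == 1
    if (!is.null(at_point) && v %in% names(at_point)) {
      pi_ <- .cell_index(at_point[[v]][1], fields$lon)
      pj <- .cell_index(at_point[[v]][2], fields$lat)
      vi <- rep(pi_, n); vj <- rep(pj, n)
    } else {
      vi <- ii; vj <- jj
    }
    lag <- lags[[v]]
    if (is.null(lag) || static) {
      k <- if (static) rep(1L, n) else ti
      val <- a[cbind(vi, vj, k)]
    } else {
      val <- vapply(seq_len(n), function(r) {
        if (is.na(vi[r]) || is.na(vj[r])) return(NA_real_)
        t1 <- as.numeric(tq[r]); t0 <- t1 - lag * 86400
        if (t0 < tnum[1] - 86400) return(NA_real_)  # window precedes raster
        sel <- tnum >= t0 & tnum <= t1
        if (!any(sel)) return(NA_real_)
        mean(a[vi[r], vj[r], which(sel)])
      }, 0)
    }
    tr <- if (!is.null(transforms) && v %in% names(transforms))
      transforms[[v]] else NULL
    if (!is.null(tr) && !is.na(tr))
      val <- switch(tr, log = log(val), log10 = log10(val),
                    log_abs = log(abs(val)), val)
    out[[v]] <- val
  }
  miss <- !stats::complete.cases(out[, vars, drop = FALSE])
  attr(out, "n_missing") <- sum(miss)
  attr(out, "meta") <- list(lags = lags, at_point = at_point,
                            transforms = transforms,
                            resolution = diff(fields$lon[1:2]))
  out
}

#' Screen covariates for collinearity
#'
#' Flags every pair of covariates with absolute Pearson correlation at or
#' above `rho_max` and every covariate with variance inflation factor at or
#' above `vif_max` (VIF computed as the diagonal of the inverse correlation
#' matrix). Flagged pairs that are temporal/spatial scale variants of the
#' same family (names differing only in a numeric suffix, e.g. `Chla_14` vs
#' `Chla_30`, `SST_SD_50` vs `SST_SD_100`) are resolved by keeping the
#' longer/larger scale — the convention of retaining the 30-day and
#' 100 km^2 versions; otherwise the later-listed variable is dropped.
#' Constant columns have undefined VIF and are flagged.
#'
#' @param mat data.frame; non-numeric columns and `mode_state` are ignored.
#' @param vif_max VIF threshold (default 3).
#' @param rho_max correlation threshold (default 0.8).
#' @return object of class `collinearity_report`: `rho` matrix, `vif` vector,
#'   `flagged_pairs`, `dropped` (with reasons), `kept`.
#' @export
screen_collinearity <- function(mat, vif_max = 3, rho_max = 0.8) {
  num <- vapply(mat, is.numeric, TRUE)
  vars <- setdiff(names(mat)[num], c("mode_state", "time"))
  stopifnot(length(vars) >= 2)
  X <- mat[, vars, drop = FALSE]
  X <- X[stats::complete.cases(X), , drop = FALSE]
  if (nrow(X) < length(vars)) stop("need at least as many rows as covariates")
  const <- vapply(X, function(v) stats::sd(v) == 0, TRUE)
  rho <- suppressWarnings(stats::cor(X))
  ## VIF_j = 1/(1 - R^2_j) from regressing column j on the others; robust to
  ## exactly collinear designs (VIF = Inf) unlike inverting the correlation
  vif <- rep(NA_real_, length(vars)); names(vif) <- vars
  for (j in which(!const)) {
    others <- setdiff(which(!const), j)
    if (!length(others)) next
    r2 <- suppressWarnings(  # perfect fits are expected for duplicated columns
      summary(stats::lm(X[[j]] ~ ., data = X[others]))$r.squared)
    vif[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }

  split_name <- function(v) {
    m <- regmatches(v, regexec("^(.*?)_([0-9]+)$", v, perl = TRUE))[[1]]
    if (length(m) == 3) list(stem = m[2], scale = as.numeric(m[3]))
    else list(stem = v, scale = NA_real_)
  }
  pairs <- which(abs(rho) >= rho_max & upper.tri(rho), arr.ind = TRUE)
  dropped <- character(0); reason <- character(0)
  if (nrow(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      a <- vars[pairs[r, 1]]; b <- vars[pairs[r, 2]]
      if (a %in% dropped || b %in% dropped) next
      sa <- split_name(a); sb <- split_name(b)
      if (identical(sa$stem, sb$stem) && !is.na(sa$scale) && !is.na(sb$scale)) {
        drop <- if (sa$scale < sb$scale) a else b
        why <- sprintf("scale variant of %s (|rho| >= %.2f); larger scale kept",
                       if (drop == a) b else a, rho_max)
      } else {
        drop <- b  # later-listed
        why <- sprintf("|rho| >= %.2f with %s; later-listed dropped", rho_max, a)
      }
      dropped <- c(dropped, drop); reason <- c(reason, why)
    }
  }
  high_vif <- vars[!is.na(vif) & vif >= vif_max & !(vars %in% dropped)]
  flagged_const <- vars[const]
  structure(list(rho = rho, vif = vif,
                 flagged_pairs = if (nrow(pairs))
                   data.frame(a = vars[pairs[, 1]], b = vars[pairs[, 2]],
                              rho = rho[pairs]) else
                   data.frame(a = character(), b = character(), rho = numeric()),
                 high_vif = high_vif,
                 constant = flagged_const,
                 dropped = data.frame(variable = dropped, reason = reason,
                                      stringsAsFactors = FALSE),
                 kept = setdiff(vars, dropped)),
            class = "collinearity_report")
}

#' @export
print.collinearity_report <- function(x, ...) {
  cat("Collinearity screen\n")
  cat("  VIF:", paste(sprintf("%s=%.2f", names(x$vif), x$vif), collapse = ", "), "\n")
  if (nrow(x$flagged_pairs)) {
    cat("  flagged pairs:\n"); print(x$flagged_pairs)
  }
  if (length(x$high_vif)) cat("  high VIF:", paste(x$high_vif, collapse = ", "), "\n")
  if (nrow(x$dropped)) { cat("  dropped:\n"); print(x$dropped) }
  invisible(x)
}
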