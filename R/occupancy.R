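#' Great-circle distance
#'
#' Haversine distance on a sphere of radius 6371 km. One degree of meridian
#' arc is pi * 6371 / 180 = 111.195 km.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in degrees (vectorised).
#' @return distance(s) in km.
#' @export
great_circle_km <- function(lon1, lat1, lon2, lat2) {
  r <- 6371
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

#' Named region masks
#'
#' A region mask is a pure predicate on (lon, lat). The `"GSACUS"` preset is
#' the Great Southern Australian Coastal Upwelling System, operationalised as
#' south of 30 deg S and east of 125 deg E.
#'
#' @param name preset name, or supply `predicate` directly.
#' @param predicate function(lon, lat) -> logical.
#' @return object of class `region_mask` (callable).
#' @examples
#' m <- region_mask("GSACUS")
#' m(130, -35)  # TRUE
#' @export
region_mask <- function(name = c("GSACUS"), predicate = NULL) {
  if (is.null(predicate)) {
    name <- match.arg(name)
    predicate <- switch(name, GSACUS = function(lon, lat) lat <= -30 & lon >= 125)
  }
  structure(predicate, class = c("region_mask", "function"))
}

#' Per-whale track metrics
#'
#' Distance is the sum of great-circle steps between consecutive regular
#' state locations, within segments only (never across transmission gaps).
#' Track duration spans first to last transmission, including gaps. Mean
#' speed divides the summed distance by the within-segment elapsed time
#' (number of summed steps x the regular step length).
#'
#' @param series a state-series data.frame (`tag_id, segment, timestamp, lon,
#'   lat`, e.g. from [as.data.frame.hssm()]) for one whale.
#' @param deployment optional list/row with `first_tx`, `last_tx` (POSIXct);
#'   when absent the series' own time span is used.
#' @param dt_hours regular step, hours (default 3).
#' @param mask optional [region_mask()]; adds `days_in_region`.
#' @return one-row data.frame: `tag_id, track_duration_days,
#'   n_state_locations, distance_km, mean_speed_kmh, days_in_region`.
#' @export
track_metrics <- function(series, deployment = NULL, dt_hours = 3, mask = NULL) {
  stopifnot(nrow(series) >= 1)
  tcol <- if ("timestamp" %in% names(series)) "timestamp" else "time"
  segcol <- if ("segment" %in% names(series)) series$segment else rep(0L, nrow(series))
  dist <- 0; nsteps <- 0L
  for (s in unique(segcol)) {
    sub <- series[segcol == s, , drop = FALSE]
    sub <- sub[order(.as_utc(sub[[tcol]])), , drop = FALSE]
    if (nrow(sub) >= 2) {
      n <- nrow(sub)
      dist <- dist + sum(great_circle_km(sub$lon[-n], sub$lat[-n],
                                         sub$lon[-1], sub$lat[-1]))
      nsteps <- nsteps + (n - 1L)
    }
  }
  if (is.null(deployment)) {
    tt <- .as_utc(series[[tcol]])
    dur <- as.numeric(difftime(max(tt), min(tt), units = "days"))
  } else {
    dur <- as.numeric(difftime(.as_utc(deployment$last_tx),
                               .as_utc(deployment$first_tx), units = "days"))
  }
  speed <- if (nsteps > 0) dist / (nsteps * dt_hours) else NA_real_
  out <- data.frame(tag_id = series$tag_id[1] %||% NA_character_,
                    track_duration_days = dur,
                    n_state_locations = nrow(series),
                    distance_km = dist,
                    mean_speed_kmh = speed,
                    stringsAsFactors = FALSE)
  if (!is.null(mask)) out$days_in_region <- region_days(series, mask)
  out
}

#' Weighted-day occupancy grid
#'
#' Counts, per cell of a regular lon/lat grid (default 0.5 degrees, cells
#' half-open `[lon0, lon0 + cell)` anchored at integer degrees), the number
#' of days each whale spent there — each regular state location contributes
#' `dt/24` of a day — then weights each whale's surface by its deployment
#' duration divided by the longest deployment duration, and sums over
#' whales. The grid total therefore equals
#' `sum_w weight_w * days_of_locations_w` exactly.
#'
#' @param series_set list of per-whale state-series data.frames (`lon, lat`),
#'   or a single combined data.frame with a `tag_id` column.
#' @param cell_deg cell size, degrees.
#' @param durations optional named numeric vector of deployment durations in
#'   days per tag; defaults to each whale's series time span.
#' @param dt_hours regular step, hours.
#' @return object of class `occupancy_grid`: data.frame `cell_lon, cell_lat,
#'   weighted_days` (cell lower-left corners) with attributes `cell_deg`,
#'   `weights`, `total`.
#' @export
occupancy <- function(series_set, cell_deg = 0.5, durations = NULL, dt_hours = 3) {
  if (is.data.frame(series_set))
    series_set <- split(series_set, series_set$tag_id)
  stopifnot(length(series_set) >= 1)
  tags <- vapply(seq_along(series_set), function(i)
    as.character(series_set[[i]]$tag_id[1] %||% names(series_set)[i] %||% i), "")
  if (is.null(durations)) {
    durations <- vapply(series_set, function(sr) {
      tcol <- if ("timestamp" %in% names(sr)) "timestamp" else "time"
      tt <- .as_utc(sr[[tcol]])
      as.numeric(difftime(max(tt), min(tt), units = "days"))
    }, 0)
    names(durations) <- tags
  }
  dmax <- max(durations)
  if (dmax <= 0) stop("longest deployment duration must be positive")
  w <- durations / dmax

  acc <- new.env(parent = emptyenv())
  per_day <- dt_hours / 24
  for (i in seq_along(series_set)) {
    sr <- series_set[[i]]
    cl <- floor(sr$lon / cell_deg) * cell_deg
    ca <- floor(sr$lat / cell_deg) * cell_deg
    key <- paste(cl, ca, sep = "|")
    tab <- tapply(rep(per_day * w[[tags[i]]], length(key)), key, sum)
    for (k in names(tab)) {
      acc[[k]] <- (acc[[k]] %||% 0) + tab[[k]]
    }
  }
  keys <- ls(acc)
  parts <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
  out <- data.frame(cell_lon = as.numeric(parts[, 1]),
                    cell_lat = as.numeric(parts[, 2]),
                    weighted_days = vapply(keys, function(k) acc[[k]], 0))
  out <- out[order(out$cell_lon, out$cell_lat), ]
  rownames(out) <- NULL
  attr(out, "cell_deg") <- cell_deg
  attr(out, "weights") <- w
  attr(out, "total") <- sum(out$weighted_days)
  class(out) <- c("occupancy_grid", "data.frame")
  out
}

#' Calendar days with at least one location in a region
#'
#' Counts distinct UTC calendar days on which the series has one or more
#' state locations satisfying the mask — the "minimum days in region"
#' summary (minimum because transmission gaps can only hide presence).
#'
#' @param series state-series data.frame with times and `lon`, `lat`.
#' @param mask a [region_mask()].
#' @return integer day count.
#' @export
region_days <- function(series, mask) {
  stopifnot(inherits(mask, "region_mask"))
  tcol <- if ("timestamp" %in% names(series)) "timestamp" else "time"
  sel <- mask(series$lon, series$lat)
  if (!any(sel)) return(0L)
  length(unique(format(.as_utc(series[[tcol]][sel]), "%Y-%m-%d", tz = "UTC")))
}

#' @export
print.occupancy_grid <- function(x, ...) {
  cat(sprintf("occupancy_grid: %d occupied cells at %.2f deg, total %.3f weighted days\n",
              nrow(x), attr(x, "cell_deg"), attr(x, "total")))
  NextMethod()
}
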