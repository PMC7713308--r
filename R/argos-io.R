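#' Read Argos-style location records from delimited text
#'
#' Expects a header with columns `tag_id, timestamp, lc, lon, lat`
#' (ISO-8601 UTC timestamps). Every well-formed row is returned — all seven
#' quality classes including Z are retained, since downstream filtering is
#' done by the state-space model's measurement error, not by discarding
#' fixes. Malformed rows (unknown class token, unparseable time, coordinates
#' out of range) are counted and reported via the `rejected` attribute, never
#' silently dropped.
#'
#' @param path file path.
#' @param sep field separator (default comma).
#' @return data.frame `tag_id, time, lc, lon, lat` with attribute `rejected`:
#'   a data.frame of line numbers and reasons. An empty file yields an empty
#'   data.frame.
#' @export
read_argos <- function(path, sep = ",") {
  stopifnot(file.exists(path))
  raw <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("tag_id", "timestamp", "lc", "lon", "lat")
  if (!all(need %in% names(raw)))
    stop("missing columns: ", paste(setdiff(need, names(raw)), collapse = ", "))
  if (nrow(raw) == 0) {
    out <- data.frame(tag_id = character(), time = .as_utc(character()),
                      lc = character(), lon = numeric(), lat = numeric())
    attr(out, "rejected") <- data.frame(line = integer(), reason = character())
    return(out)
  }
  time <- as.POSIXct(raw$timestamp, tz = "UTC",
                     tryFormats = c("%Y-%m-%dT%H:%M:%SZ", "%Y-%m-%dT%H:%M:%S",
                                    "%Y-%m-%d %H:%M:%S", "%Y-%m-%d"))
  lon <- suppressWarnings(as.numeric(raw$lon))
  lat <- suppressWarnings(as.numeric(raw$lat))
  reason <- rep(NA_character_, nrow(raw))
  reason[!(raw$lc %in% ARGOS_CLASSES)] <- "unknown location class"
  reason[is.na(time) & is.na(reason)] <- "unparseable timestamp"
  bad_coord <- is.na(lon) | is.na(lat) | !is.finite(lon) | !is.finite(lat) |
    lon < -180 | lon > 180 | lat < -90 | lat > 90
  reason[bad_coord & is.na(reason)] <- "coordinate out of range"
  ok <- is.na(reason)
  out <- data.frame(tag_id = raw$tag_id[ok], time = time[ok], lc = raw$lc[ok],
                    lon = lon[ok], lat = lat[ok], stringsAsFactors = FALSE)
  attr(out, "rejected") <- data.frame(line = which(!ok) + 1L,  # +1 for header
                                      reason = reason[!ok], stringsAsFactors = FALSE)
  out
}

#' Write Argos-style observations as delimited text
#' @param observations data.frame with `tag_id, time, lc, lon, lat`.
#' @param path output file.
#' @export
write_argos <- function(observations, path) {
  df <- data.frame(tag_id = observations$tag_id,
                   timestamp = format(.as_utc(observations$time),
                                      "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
                   lc = observations$lc,
                   lon = observations$lon, lat = observations$lat)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Split a tag's observations into analysis-ready track segments
#'
#' Tracks are split wherever the interval between consecutive received fixes
#' strictly exceeds `gap_hours` (a gap of exactly 48.0 h does not split), and
#' resulting segments with fewer than `min_obs` observations are discarded.
#' Fix quality class plays no role in gap timing: all retained classes count.
#'
#' @param observations data.frame for a single tag (`time, lon, lat, lc,
#'   tag_id`); sorted by time if not already (stable sort, so duplicate
#'   timestamps keep their input order).
#' @param gap_hours split threshold in hours (default 48).
#' @param min_obs minimum observations per retained segment (default 20).
#' @return list of `track_segment` data.frames, each carrying attributes
#'   `tag_id` and `segment` (dense indices from 0).
#' @export
segment_track <- function(observations, gap_hours = 48, min_obs = 20) {
  if (is.null(observations) || nrow(observations) == 0) return(list())
  if (length(unique(observations$tag_id)) > 1)
    stop("segment_track expects observations from a single tag")
  o <- observations[order(.as_utc(observations$time)), , drop = FALSE]  # stable
  dth <- diff(as.numeric(.as_utc(o$time))) / 3600
  grp <- cumsum(c(0, dth > gap_hours))
  segs <- split(seq_len(nrow(o)), grp)
  out <- list()
  idx <- 0L
  for (s in segs) {
    if (length(s) < min_obs) next
    seg <- o[s, , drop = FALSE]
    rownames(seg) <- NULL
    attr(seg, "tag_id") <- o$tag_id[1]
    attr(seg, "segment") <- idx
    class(seg) <- c("track_segment", "data.frame")
    out[[length(out) + 1L]] <- seg
    idx <- idx + 1L
  }
  out
}

#' Mean interval between successive fixes
#'
#' Arithmetic mean, in hours, of the intervals between consecutive
#' observations; the quantity used to choose the regular state-space time
#' step (a 2.3-h mean transmission rate motivates a 3-h step).
#'
#' @param observations time-ordered data.frame with a `time` column.
#' @return hours (numeric scalar).
#' @export
mean_interval <- function(observations) {
  tt <- sort(as.numeric(.as_utc(observations$time)))
  if (length(tt) < 2) stop("mean_interval needs at least 2 observations")
  mean(diff(tt)) / 3600
}
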