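#' Gridded seascape field set
#'
#' A light container for named environmental rasters on a shared regular
#' lon/lat grid with a (possibly length-1, i.e. static) time axis. Values are
#' stored as `[lon, lat, time]` arrays.
#'
#' @param lon,lat cell-center coordinate vectors, strictly increasing,
#'   regular spacing.
#' @param time POSIXct vector of time-slice centers (length 1 for static
#'   fields), strictly increasing.
#' @param data named list of numeric arrays, each `length(lon) x length(lat)`
#'   by `length(time)` or by 1 (static variable on a dynamic set).
#' @param units optional named character vector of units per variable.
#' @return object of class `seascape_fields`.
#' @export
seascape_fields <- function(lon, lat, time, data, units = NULL) {
  stopifnot(length(lon) > 1, length(lat) > 1, !is.unsorted(lon, strictly = TRUE),
            !is.unsorted(lat, strictly = TRUE), is.list(data), length(names(data)) == length(data))
  time <- .as_utc(time)
  if (length(time) > 1 && is.unsorted(as.numeric(time), strictly = TRUE))
    stop("time axis must be strictly increasing")
  for (v in names(data)) {
    d <- dim(data[[v]])
    if (is.null(d) || length(d) != 3 || d[1] != length(lon) || d[2] != length(lat) ||
        !(d[3] %in% c(1L, length(time))))
      stop(sprintf("field '%s' must be a [lon, lat, time] array matching the axes", v))
  }
  structure(list(lon = lon, lat = lat, time = time, data = data, units = units),
            class = "seascape_fields")
}

#' @export
print.seascape_fields <- function(x, ...) {
  cat(sprintf("seascape_fields: %d x %d grid (%.2f deg), %d time slice(s)\n",
              length(x$lon), length(x$lat), diff(x$lon[1:2]), length(x$time)))
  cat("variables:", paste(names(x$data), collapse = ", "), "\n")
  invisible(x)
}

#' Write/read a field set as long-format delimited text
#'
#' Serialises every cell of every variable as rows `var, lon, lat, time,
#' value` so field sets round-trip through plain text.
#'
#' @param fields a [seascape_fields()] object.
#' @param path output file.
#' @export
write_fields <- function(fields, path) {
  stopifnot(inherits(fields, "seascape_fields"))
  rows <- lapply(names(fields$data), function(v) {
    a <- fields$data[[v]]
    nt <- dim(a)[3]
    tt <- if (nt == 1) fields$time[1] else fields$time
    g <- expand.grid(lon = fields$lon, lat = fields$lat, time = tt,
                     KEEP.OUT.ATTRS = FALSE)
    data.frame(var = v, lon = g$lon, lat = g$lat,
               time = format(g$time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
               value = as.vector(a), stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fields
#' @param path input file written by [write_fields()].
#' @export
read_fields <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lon <- sort(unique(df$lon)); lat <- sort(unique(df$lat))
  time <- .as_utc(sort(unique(as.POSIXct(df$time, tz = "UTC",
                                         format = "%Y-%m-%dT%H:%M:%SZ"))))
  data <- list()
  for (v in unique(df$var)) {
    sub <- df[df$var == v, ]
    tt <- unique(sub$time)
    nt <- length(tt)
    a <- array(NA_real_, c(length(lon), length(lat), nt))
    i <- match(sub$lon, lon); j <- match(sub$lat, lat)
    k <- match(sub$time, sort(tt))
    a[cbind(i, j, k)] <- sub$value
    data[[v]] <- a
  }
  seascape_fields(lon, lat, time, data)
}
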