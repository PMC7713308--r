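#' Argos measurement-error model
#'
#' Per-class scales (degrees longitude and latitude) and degrees of freedom of
#' the heavy-tailed t-distributed location error assigned to each Argos
#' quality class. The same table is used by the track simulator (to corrupt
#' true positions) and by the state-space model (as the fixed measurement
#' density), matching the common practice of fixing, not estimating, Argos
#' error scales.
#'
#' Default magnitudes follow published t-distribution calibrations of Argos
#' errors (scale parameters of a few hundred metres for class 3 growing to
#' roughly 2 km for class B, longitude worse than latitude, with heavy tails
#' so multi-kilometre outliers still occur), and class Z — uncalibrated in
#' the literature — set to twice class B. Note these are t *scale*
#' parameters, not percentile error radii, which are several times larger
#' under the heavy tails. All values are configuration, not constants of the
#' method.
#'
#' @param scale_lon,scale_lat named numeric vectors of t scale parameters in
#'   degrees, one entry per class `"3","2","1","0","A","B","Z"`.
#' @param df named numeric vector of t degrees of freedom per class.
#' @return an object of class `argos_error_model`.
#' @examples
#' em <- argos_error_model()
#' em$scale_lat[["B"]]
#' @export
argos_error_model <- function(scale_lon = c("3" = 0.0030, "2" = 0.0035, "1" = 0.0067,
                                            "0" = 0.0135, "A" = 0.0135, "B" = 0.021, "Z" = 0.042),
                              scale_lat = c("3" = 0.0025, "2" = 0.0028, "1" = 0.0044,
                                            "0" = 0.0090, "A" = 0.0090, "B" = 0.0127, "Z" = 0.0254),
                              df = c("3" = 4, "2" = 3, "1" = 2,
                                     "0" = 2, "A" = 2, "B" = 2, "Z" = 2)) {
  for (v in list(scale_lon, scale_lat, df)) {
    stopifnot(all(ARGOS_CLASSES %in% names(v)), all(v[ARGOS_CLASSES] > 0))
  }
  scale_lon <- scale_lon[ARGOS_CLASSES]; scale_lat <- scale_lat[ARGOS_CLASSES]
  df <- df[ARGOS_CLASSES]
  # accuracy must not improve down the class ladder (Z excluded: unranked grade)
  ord <- c("3", "2", "1", "0", "A", "B")
  if (is.unsorted(scale_lon[ord]) || is.unsorted(scale_lat[ord]))
    stop("error scales must be non-decreasing from class 3 to class B")
  structure(list(scale_lon = scale_lon, scale_lat = scale_lat, df = df),
            class = "argos_error_model")
}

# draw n t-distributed error pairs for the given classes
.draw_argos_error <- function(em, lc) {
  n <- length(lc)
  cbind(lon = stats::rt(n, em$df[lc]) * em$scale_lon[lc],
        lat = stats::rt(n, em$df[lc]) * em$scale_lat[lc])
}

# measurement log-density of residuals under the class t model
.argos_logdens <- function(em, lc, dlon, dlat) {
  sl <- em$scale_lon[lc]; sa <- em$scale_lat[lc]; v <- em$df[lc]
  stats::dt(dlon / sl, v, log = TRUE) - log(sl) +
    stats::dt(dlat / sa, v, log = TRUE) - log(sa)
}
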