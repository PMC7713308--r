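#' @keywords internal
#' @useDynLib arstrack, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# hours between two POSIXct instants
.hours_between <- function(t0, t1) as.numeric(difftime(t1, t0, units = "hours"))

.as_utc <- function(x) {
  if (inherits(x, "POSIXct")) return(as.POSIXct(as.numeric(x), origin = "1970-01-01", tz = "UTC"))
  as.POSIXct(x, tz = "UTC")
}

# truncated normal draw via inverse CDF; numerically guarded
.rtnorm <- function(mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  if (phi - plo < 1e-12) {
    # mass effectively outside (lo, hi): clamp to nearest bound
    return(if (mean < lo) lo + 1e-9 else hi - 1e-9)
  }
  stats::qnorm(stats::runif(1, plo, phi), mean, sd)
}

#' Derive a stage seed from a global seed
#'
#' Every stochastic stage of the pipeline consumes a seed computed
#' deterministically from the global seed and the stage name, so reruns with
#' the same global seed are reproducible stage by stage while stages remain
#' decoupled.
#'
#' @param seed global integer seed.
#' @param stage character stage name.
#' @return an integer seed in [0, 2^31).
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 1009) %% 2147483647)
}

#' Argos location quality classes
#'
#' The seven Argos quality classes in decreasing nominal accuracy order.
#' Class Z (invalid-grade) is retained throughout the pipeline; the
#' state-space model absorbs its error rather than prefiltering.
#' @export
ARGOS_CLASSES <- c("3", "2", "1", "0", "A", "B", "Z")
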