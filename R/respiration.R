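# Breath-feature detection and instantaneous respiratory phase from a nasal
# airflow trace.

#' Detect breath features from a nasal airflow trace
#'
#' The trace is mean-centered and smoothed (moving average), then inhale
#' onsets are taken as rising zero crossings, exhale onsets as falling zero
#' crossings, and the inhale peak / exhale trough as the extremum between the
#' surrounding crossings. Events interleave strictly in time:
#' inhale onset < peak < exhale onset < trough < next inhale onset.
#'
#' @param airflow numeric airflow vector (positive = inhale).
#' @param sampling_rate Hz.
#' @param smooth_s smoothing kernel in seconds (default 0.1).
#' @param start_time time of the first sample (s).
#' @return a `breath_features` list: `inhale_onsets`, `exhale_onsets`,
#'   `peak_times`, `trough_times` (all s), `peak_volumes`, `trough_volumes`.
#' @export
detect_breaths <- function(airflow, sampling_rate, smooth_s = 0.1,
                           start_time = 0) {
  stopifnot(sampling_rate > 0)
  x <- airflow - mean(airflow)
  if (stats::sd(x) == 0) {
    warning("flat airflow signal: no breath features detected")
    return(structure(list(inhale_onsets = numeric(0), exhale_onsets = numeric(0),
                          peak_times = numeric(0), trough_times = numeric(0),
                          peak_volumes = numeric(0), trough_volumes = numeric(0)),
                     class = "breath_features"))
  }
  xs <- moving_average(x, kernel_samples(smooth_s, sampling_rate))
  s <- sign(xs)
  s[s == 0] <- 1
  d <- diff(s)
  rising <- which(d > 0)        # last sample before the crossing
  falling <- which(d < 0)
  t_of <- function(i) start_time + (i - 1) / sampling_rate
  # linear interpolation of the crossing time between samples i and i+1
  cross_time <- function(i) {
    frac <- xs[i] / (xs[i] - xs[i + 1])
    t_of(i) + frac / sampling_rate
  }
  inhale <- vapply(rising, cross_time, numeric(1))
  exhale <- vapply(falling, cross_time, numeric(1))

  peaks <- numeric(0); peak_vol <- numeric(0)
  troughs <- numeric(0); trough_vol <- numeric(0)
  for (i in seq_along(rising)) {
    nxt <- falling[falling > rising[i]]
    if (length(nxt)) {
      seg <- (rising[i] + 1):nxt[1]
      j <- seg[which.max(xs[seg])]
      peaks <- c(peaks, t_of(j)); peak_vol <- c(peak_vol, xs[j])
    }
  }
  for (i in seq_along(falling)) {
    nxt <- rising[rising > falling[i]]
    if (length(nxt)) {
      seg <- (falling[i] + 1):nxt[1]
      j <- seg[which.min(xs[seg])]
      troughs <- c(troughs, t_of(j)); trough_vol <- c(trough_vol, xs[j])
    }
  }
  structure(list(inhale_onsets = inhale, exhale_onsets = exhale,
                 peak_times = peaks, trough_times = troughs,
                 peak_volumes = peak_vol, trough_volumes = trough_vol),
            class = "breath_features")
}

#' @export
print.breath_features <- function(x, ...) {
  cat(sprintf("<breath_features> %d inhales, %d exhales\n",
              length(x$inhale_onsets), length(x$exhale_onsets)))
  invisible(x)
}

#' Instantaneous respiratory phase
#'
#' Phase of the analytic (Hilbert) signal of the mean-centered airflow trace,
#' in `(-pi, pi]`. Convention: phase 0 at the inhale peak, `+pi/2` at the
#' inhale-to-exhale transition, and `+-pi` at the exhale trough.
#'
#' @param airflow numeric airflow vector.
#' @return phase vector in radians, same length.
#' @export
respiratory_phase <- function(airflow) {
  x <- airflow - mean(airflow)
  Arg(hilbert_analytic(x))
}
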