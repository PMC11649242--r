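#' Piecewise-linear calcium event waveform
#'
#' Renders a single calcium transient as a triangular ΔF/F₀ waveform: a linear
#' rise to `amp` followed by a linear return to baseline. The 10–90% rise time
#' of a linear ramp is 80% of its full duration, so the configured kinetics
#' map exactly onto the ramp durations (`T_up = rise_10_90 / 0.8`,
#' `T_down = decay_90_10 / 0.8`). A piecewise-linear shape is used because it
#' can realise any combination of rise and decay times, including rise slower
#' than decay as observed in astrocyte arborizations.
#'
#' @param t numeric vector of times (s).
#' @param onset_s event onset time (s).
#' @param amp peak amplitude (ΔF/F₀).
#' @param rise_10_90_s target 10–90% rise time (s).
#' @param decay_90_10_s target 90–10% decay time (s).
#' @return numeric vector of ΔF/F₀ values, 0 outside the event.
#' @export
#' @examples
#' t <- seq(0, 30, by = 0.5)
#' w <- event_waveform(t, onset_s = 5, amp = 2, rise_10_90_s = 5.7,
#'                     decay_90_10_s = 4.8)
#' max(w)
event_waveform <- function(t, onset_s, amp, rise_10_90_s, decay_90_10_s) {
  stopifnot(rise_10_90_s > 0, decay_90_10_s > 0, amp > 0)
  t_up <- rise_10_90_s / 0.8
  t_down <- decay_90_10_s / 0.8
  s <- t - onset_s
  w <- numeric(length(t))
  up <- s >= 0 & s < t_up
  dn <- s >= t_up & s < t_up + t_down
  w[up] <- amp * s[up] / t_up
  w[dn] <- amp * (1 - (s[dn] - t_up) / t_down)
  w
}

#' Measure 10-90% rise and 90-10% decay of a sampled waveform
#'
#' Kinetics are measured relative to a baseline of 0 with linear
#' interpolation between samples: the rise time is the interval between the
#' upward 10% and 90% crossings of the peak amplitude before the peak, the
#' decay time the interval between the downward 90% and 10% crossings after
#' it. Used by the generator's self-calibration checks; for detected events
#' in real traces see [event_kinetics()].
#'
#' @param t sample times (s).
#' @param w sampled waveform values.
#' @return named numeric vector `c(rise_10_90_s=, decay_90_10_s=)`; decay is
#'   `NA` (censored) if the waveform never returns below 10% of peak.
#' @export
measure_waveform_times <- function(t, w) {
  stopifnot(length(t) == length(w), length(t) >= 3)
  ipk <- which.max(w)
  amp <- w[ipk]
  if (amp <= 0) return(c(rise_10_90_s = NA_real_, decay_90_10_s = NA_real_))
  lo <- 0.1 * amp
  hi <- 0.9 * amp
  rise <- cross_time(t, w, hi, ipk, dir = "up") -
    cross_time(t, w, lo, ipk, dir = "up")
  after <- seq(ipk, length(w))
  dec <- if (any(w[after] <= lo)) {
    cross_down(t, w, lo, ipk) - cross_down(t, w, hi, ipk)
  } else NA_real_
  c(rise_10_90_s = rise, decay_90_10_s = dec)
}

# linear interpolation of the time at which w crosses `level` between two
# consecutive samples (handles rising and falling segments alike)
#' @keywords internal
lin_cross <- function(t1, t2, w1, w2, level) {
  if (w2 == w1) return(t1)
  t1 + (level - w1) * (t2 - t1) / (w2 - w1)
}

# last upward crossing of `level` at or before index ipk
#' @keywords internal
cross_time <- function(t, w, level, ipk, dir = "up") {
  below <- which(w[seq_len(ipk)] < level)
  if (!length(below)) return(t[1])
  i <- max(below)                      # last sample below level before peak
  if (i == ipk) return(t[ipk])
  lin_cross(t[i], t[i + 1], w[i], w[i + 1], level)
}

# first downward crossing of `level` at or after index ipk
#' @keywords internal
cross_down <- function(t, w, level, ipk) {
  idx <- seq(ipk, length(w))
  below <- which(w[idx] <= level)
  if (!length(below)) return(NA_real_)
  j <- idx[min(below)]                 # first sample at/below level after peak
  if (j == ipk) return(t[ipk])
  lin_cross(t[j - 1], t[j], w[j - 1], w[j], level)
}
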