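#' Extract a normalized ROI trace from a functional movie
#'
#' Averages the movie over the ROI pixels frame by frame and normalizes to
#' ΔF/F₀ with F₀ the mean fluorescence of the 10 s window preceding stimulus
#' onset. Baseline mean and SD of the ΔF/F₀ trace over that window are stored
#' for event detection. The normalization makes the trace invariant to any
#' positive rescaling of the raw movie.
#'
#' @param movie ny x nx x nframes numeric array.
#' @param roi logical matrix (ny x nx) or integer vector of 1-based linear
#'   pixel indices into a frame.
#' @param frame_interval_s frame interval (s). Frame k is timestamped
#'   `(k-1) * frame_interval_s`.
#' @param stim_onset_s,stim_end_s stimulation window (s).
#' @param baseline_s baseline duration before onset (s, default 10).
#' @return object of class `trace`: list with `values` (ΔF/F₀ per frame),
#'   `times`, `frame_interval_s`, `stim_onset_s`, `stim_end_s`,
#'   `baseline_mean`, `baseline_sd`, `f0`.
#' @export
extract_trace <- function(movie, roi, frame_interval_s, stim_onset_s,
                          stim_end_s, baseline_s = 10) {
  stopifnot(length(dim(movie)) == 3, frame_interval_s > 0)
  npx_frame <- dim(movie)[1] * dim(movie)[2]
  nt <- dim(movie)[3]
  idx <- if (is.logical(roi)) which(roi) else as.integer(roi)
  if (!length(idx)) stop("ROI is empty")
  m <- matrix(movie, npx_frame, nt)
  f <- colMeans(m[idx, , drop = FALSE])
  trace_from_f(f, frame_interval_s, stim_onset_s, stim_end_s, baseline_s)
}

#' @keywords internal
#' ΔF/F₀ trace from a raw mean-fluorescence series (shared by
#' [extract_trace()] and the pipeline's flat-matrix extraction).
trace_from_f <- function(f, frame_interval_s, stim_onset_s, stim_end_s,
                         baseline_s = 10) {
  times <- (seq_along(f) - 1) * frame_interval_s
  bl <- times >= stim_onset_s - baseline_s & times < stim_onset_s
  if (!any(bl)) stop("no baseline frames before stimulus onset")
  f0 <- mean(f[bl])
  if (!is.finite(f0) || f0 <= 0)
    stop("baseline fluorescence F0 is not positive; cell excluded")
  v <- (f - f0) / f0
  structure(list(values = v, times = times,
                 frame_interval_s = frame_interval_s,
                 stim_onset_s = stim_onset_s, stim_end_s = stim_end_s,
                 baseline_mean = mean(v[bl]), baseline_sd = sd(v[bl]),
                 f0 = f0, baseline_frames = which(bl)),
            class = "trace")
}

#' Build a trace object from an already-normalized ΔF/F₀ series
#'
#' Convenience constructor used by simulations and tests that work directly
#' in ΔF/F₀ units without a pixel movie.
#'
#' @param values ΔF/F₀ per frame.
#' @inheritParams extract_trace
#' @return a `trace` object.
#' @export
as_trace <- function(values, frame_interval_s, stim_onset_s, stim_end_s,
                     baseline_s = 10) {
  times <- (seq_along(values) - 1) * frame_interval_s
  bl <- times >= stim_onset_s - baseline_s & times < stim_onset_s
  if (!any(bl)) stop("no baseline frames before stimulus onset")
  structure(list(values = values, times = times,
                 frame_interval_s = frame_interval_s,
                 stim_onset_s = stim_onset_s, stim_end_s = stim_end_s,
                 baseline_mean = mean(values[bl]),
                 baseline_sd = sd(values[bl]),
                 f0 = 1, baseline_frames = which(bl)),
            class = "trace")
}

#' Detect calcium events in a ΔF/F₀ trace
#'
#' An event starts at the first of at least `min_consec` consecutive frames
#' whose value exceeds the baseline mean plus `k_sd` baseline standard
#' deviations, inside the search window, and ends when the trace falls back
#' below that threshold. The amplitude is the maximum within the event. With
#' `window = "response"` the search runs from stimulus onset to the end of
#' the movie; `window = "baseline"` runs the same detector on a pre-stimulus
#' window of equal length (basal activity).
#'
#' @param trace a `trace` object.
#' @param k_sd threshold in baseline SDs (default 3).
#' @param min_consec minimum consecutive supra-threshold frames (default 2).
#' @param window `"response"` or `"baseline"`.
#' @param threshold optional explicit threshold (ΔF/F₀), overriding the
#'   baseline rule (needed for noiseless traces whose baseline SD is 0).
#' @return list with `events` (data.frame: onset_s, end_s, peak_s,
#'   amplitude, n_frames) and `active` (any event found).
#' @export
detect_events <- function(trace, k_sd = 3, min_consec = 2L,
                          window = c("response", "baseline"),
                          threshold = NULL) {
  stopifnot(inherits(trace, "trace"))
  window <- match.arg(window)
  if (is.null(threshold)) {
    if (!is.finite(trace$baseline_sd) || trace$baseline_sd <= 0)
      stop("degenerate trace: baseline SD is zero; supply `threshold`")
    threshold <- trace$baseline_mean + k_sd * trace$baseline_sd
  }
  t <- trace$times
  if (window == "response") {
    in_win <- t >= trace$stim_onset_s
  } else {
    resp_len <- max(t) + trace$frame_interval_s - trace$stim_onset_s
    in_win <- t < trace$stim_onset_s & t >= trace$stim_onset_s - resp_len
  }
  idx <- which(in_win)
  above <- trace$values[idx] > threshold
  ev <- run_events(above, min_consec)
  events <- if (nrow(ev)) {
    data.frame(
      onset_s = t[idx[ev$start]],
      end_s = t[idx[ev$end]],
      peak_s = vapply(seq_len(nrow(ev)), function(k) {
        seg <- idx[ev$start[k]:ev$end[k]]
        t[seg[which.max(trace$values[seg])]]
      }, numeric(1)),
      amplitude = vapply(seq_len(nrow(ev)), function(k) {
        max(trace$values[idx[ev$start[k]:ev$end[k]]])
      }, numeric(1)),
      n_frames = ev$end - ev$start + 1L)
  } else {
    data.frame(onset_s = numeric(), end_s = numeric(), peak_s = numeric(),
               amplitude = numeric(), n_frames = integer())
  }
  list(events = events, active = nrow(events) > 0, threshold = threshold)
}

#' @keywords internal
#' Runs of TRUE of length >= min_consec in a logical vector.
run_events <- function(above, min_consec) {
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_consec
  data.frame(start = starts[keep], end = ends[keep])
}

#' Event kinetics: latency, 10-90% rise, 90-10% decay
#'
#' Rise time is measured between the upward 10% and 90% crossings of the
#' event amplitude on the rising limb, decay time between the downward 90%
#' and 10% crossings after the peak, both with linear interpolation between
#' frames (frame intervals are coarse relative to the reported effects).
#' Amplitudes are measured relative to the baseline mean. If the trace never
#' returns below 10% the decay is censored (`NA`).
#'
#' @param trace a `trace` object.
#' @param event one row of the `events` data.frame from [detect_events()].
#' @return named list: `latency_s` (onset minus stimulus onset),
#'   `rise_10_90_s`, `decay_90_10_s` (NA when censored).
#' @export
event_kinetics <- function(trace, event) {
  stopifnot(inherits(trace, "trace"), nrow(event) == 1)
  t <- trace$times
  v <- trace$values - trace$baseline_mean
  ipk <- which.min(abs(t - event$peak_s))
  # search back from the peak to the last sub-10% frame for the rising limb
  km <- measure_limb_times(t, v, ipk)
  list(latency_s = event$onset_s - trace$stim_onset_s,
       rise_10_90_s = km[["rise_10_90_s"]],
       decay_90_10_s = km[["decay_90_10_s"]])
}

#' @keywords internal
#' Rise/decay around a given peak index on a baseline-subtracted trace.
measure_limb_times <- function(t, v, ipk) {
  amp <- v[ipk]
  if (amp <= 0)
    return(c(rise_10_90_s = NA_real_, decay_90_10_s = NA_real_))
  lo <- 0.1 * amp
  hi <- 0.9 * amp
  rise <- cross_time(t, v, hi, ipk) - cross_time(t, v, lo, ipk)
  after <- seq(ipk, length(v))
  dec <- if (any(v[after] <= lo))
    cross_down(t, v, lo, ipk) - cross_down(t, v, hi, ipk) else NA_real_
  c(rise_10_90_s = rise, decay_90_10_s = dec)
}

#' Analytic false-positive rate of the event detector on pure noise
#'
#' For i.i.d. Gaussian noise, the probability that a frame exceeds the
#' detection threshold estimated from `n_baseline` baseline frames (mean +
#' `k_sd` sample SDs) is not the naive Gaussian tail: the threshold itself is
#' random. Conditional on the estimated mean and SD, a frame exceeds the
#' threshold with probability `pnorm(-(m + k*s))` (noise in unit-SD scale);
#' this function integrates the per-trace probability of at least one run of
#' `min_consec` consecutive exceedances over the sampling distribution of
#' `(m, s)` (normal x scaled-chi) by Gauss-Legendre-style quadrature on a
#' fine grid. Within-trace frames are treated as independent given the
#' threshold, and runs counted by the standard `1 - (1 - p^c)^(n - c + 1)`
#' approximation, accurate for small p.
#'
#' @param n_frames number of frames searched for events.
#' @param n_baseline number of baseline frames used to estimate the
#'   threshold.
#' @param k_sd threshold multiplier (default 3).
#' @param min_consec run length required (default 2).
#' @return expected per-trace false-positive probability.
#' @export
fp_rate_analytic <- function(n_frames, n_baseline, k_sd = 3, min_consec = 2L) {
  stopifnot(n_frames > min_consec, n_baseline > 2)
  nb <- n_baseline
  # grid over the baseline sample mean (normal) and sample SD (chi)
  mg <- seq(-5, 5, length.out = 201) / sqrt(nb)
  wm <- stats::dnorm(mg * sqrt(nb)) * sqrt(nb)
  wm <- wm * (mg[2] - mg[1])
  sg <- seq(0.2, 2.5, length.out = 401)
  df <- nb - 1
  # density of s: s^2 * df / sigma^2 ~ chisq(df), sigma = 1
  ws <- stats::dchisq(sg^2 * df, df) * 2 * sg * df
  ws <- ws * (sg[2] - sg[1])
  p_exceed <- outer(mg, sg, function(m, s) pnorm(-(m + k_sd * s)))
  p_trace <- 1 - (1 - p_exceed^min_consec)^(n_frames - min_consec + 1)
  as.numeric(wm %*% p_trace %*% ws)
}

#' Build the per-ROI event table for a segmented, traced population
#'
#' @param traces named list of lists: per astrocyte, entries `soma`, `arbor`
#'   and `domains` (list of `trace` objects, named by domain id).
#' @param segs named list of `segmentation` objects (same names).
#' @param k_sd,min_consec detector settings.
#' @return data.frame: astrocyte_id, roi_type (soma|arbor|domain), roi_id,
#'   active, onset_s, amplitude, rise_s, decay_s, latency_s, radius_um.
#' @export
event_table <- function(traces, segs, k_sd = 3, min_consec = 2L) {
  rows <- list()
  for (id in names(traces)) {
    tr <- traces[[id]]
    seg <- segs[[id]]
    add <- function(trace, roi_type, roi_id, radius_um) {
      det <- detect_events(trace, k_sd, min_consec)
      if (det$active) {
        ev <- det$events[which.max(det$events$amplitude), ]
        first <- det$events[1, ]
        kin <- event_kinetics(trace, ev)
        data.frame(astrocyte_id = as.integer(id), roi_type = roi_type,
                   roi_id = roi_id, active = TRUE,
                   onset_s = first$onset_s, amplitude = ev$amplitude,
                   rise_s = kin$rise_10_90_s, decay_s = kin$decay_90_10_s,
                   latency_s = first$onset_s - trace$stim_onset_s,
                   radius_um = radius_um, stringsAsFactors = FALSE)
      } else {
        data.frame(astrocyte_id = as.integer(id), roi_type = roi_type,
                   roi_id = roi_id, active = FALSE, onset_s = NA_real_,
                   amplitude = NA_real_, rise_s = NA_real_,
                   decay_s = NA_real_, latency_s = NA_real_,
                   radius_um = radius_um, stringsAsFactors = FALSE)
      }
    }
    rows[[length(rows) + 1L]] <- add(tr$soma, "soma", "soma", 0)
    rows[[length(rows) + 1L]] <- add(tr$arbor, "arbor", "arbor", NA_real_)
    for (d in names(tr$domains)) {
      rad <- seg$domains$radius_um[match(d, seg$domains$domain_id)]
      rows[[length(rows) + 1L]] <- add(tr$domains[[d]], "domain", d, rad)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
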