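#' @title Pressure processing and image synchronization
#' @description Filtering, acquisition-window detection, calibration, beat
#'   segmentation, area-pressure alignment and loop construction.
#' @name hemodynamics
NULL

#' Zero-phase low-pass filtering of an LV pressure trace
#'
#' 4th-order Butterworth applied forward-backward (zero phase lag), unity DC
#' gain. The sampling rate is inferred from the time column and must be
#' uniform.
#'
#' @param trace tibble with columns `t_s`, `p_mmHg`.
#' @param cutoff_Hz low-pass cutoff (Hz), below Nyquist.
#' @return filtered trace (same columns).
#' @export
filter_pressure <- function(trace, cutoff_Hz = 30) {
  fs <- infer_fs(trace$t_s, what = "pressure trace")
  if (cutoff_Hz >= fs / 2) abort("cutoff must be below the Nyquist frequency")
  bf <- signal::butter(4, cutoff_Hz / (fs / 2), type = "low")
  out <- trace
  out$p_mmHg <- filtfilt_padded(bf, trace$p_mmHg)
  attr(out, "calibration_state") <- "filtered"
  out
}

#' Locate the image-acquisition window on a raw pressure trace
#'
#' MRI acquisition superimposes a high-frequency noise burst on the unfiltered
#' pressure recording; the window is found where the band-limited RMS over a
#' sliding 100 ms window exceeds `k` times the quiet-segment (pre-acquisition)
#' RMS, estimated as a low quantile of the sliding RMS itself.
#'
#' @param trace raw (unfiltered) tibble with `t_s`, `p_mmHg`.
#' @param k detection factor (default 3).
#' @param highpass_Hz high-pass edge isolating the burst band.
#' @param window_s sliding RMS window length (s).
#' @return `c(start_s, end_s)` of the longest supra-threshold run.
#' @export
detect_acquisition_window <- function(trace, k = 3, highpass_Hz = 80,
                                      window_s = 0.1) {
  fs <- infer_fs(trace$t_s, what = "pressure trace")
  if (!is.finite(k)) abort("non-finite detection factor k; supply the window manually")
  bf <- signal::butter(4, highpass_Hz / (fs / 2), type = "high")
  hp <- filtfilt_padded(bf, trace$p_mmHg)
  n_win <- max(3L, round(window_s * fs))
  ms <- as.numeric(stats::filter(hp^2, rep(1 / n_win, n_win), sides = 2))
  rms <- sqrt(ms)
  ok <- !is.na(rms)
  # the quiet pre-acquisition segment occupies the low tail of the sliding
  # RMS distribution; its median is estimated by a low quantile of the whole
  # record (the burst typically covers most of it)
  baseline <- quantile(rms[ok], 0.10, names = FALSE)
  above <- ok & rms > k * baseline
  if (!any(above)) {
    abort("no acquisition noise burst found; supply the acquisition window manually")
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  c(start_s = trace$t_s[starts[best]], end_s = trace$t_s[ends[best]])
}

#' Calibrate a pressure trace against reference pressures
#'
#' Fits the affine map that carries the mean per-beat minimum and maximum
#' pressure of the pre-acquisition segment onto the reference end-diastolic
#' and peak-systolic pressures, then applies it to the whole trace.
#'
#' @param trace tibble with `t_s`, `p_mmHg` (filter first for stable beat
#'   extremes).
#' @param pre_window `c(start, end)` (s) of the pre-acquisition segment; must
#'   contain at least 2 complete beats.
#' @param reference named vector `c(ed = ..., peak = ...)` (mmHg).
#' @return calibrated trace; attribute `calibration = list(gain, offset)`.
#' @export
calibrate_pressure <- function(trace, pre_window, reference) {
  if (is.null(names(reference)) || !all(c("ed", "peak") %in% names(reference))) {
    abort("reference must be a named vector with elements 'ed' and 'peak'")
  }
  pre <- trace |> dplyr::filter(.data$t_s >= pre_window[1], .data$t_s <= pre_window[2])
  if (nrow(pre) < 10) abort("pre-acquisition window is empty or too short")
  beats <- segment_beats(pre)
  if (nrow(beats) < 2) abort("pre-acquisition window must contain at least 2 beats")
  idx <- beat_index_at(pre$t_s, beats)
  per_beat <- pre |>
    mutate(beat = idx) |>
    dplyr::filter(!is.na(.data$beat)) |>
    dplyr::group_by(.data$beat) |>
    dplyr::summarise(pmin = min(.data$p_mmHg), pmax = max(.data$p_mmHg), .groups = "drop")
  obs_ed <- mean(per_beat$pmin)
  obs_peak <- mean(per_beat$pmax)
  if (abs(obs_peak - obs_ed) < 1e-9) abort("degenerate pre-window pressures")
  gain <- (reference[["peak"]] - reference[["ed"]]) / (obs_peak - obs_ed)
  offset <- reference[["ed"]] - gain * obs_ed
  out <- trace
  out$p_mmHg <- gain * trace$p_mmHg + offset
  attr(out, "calibration") <- list(gain = gain, offset = offset)
  attr(out, "calibration_state") <- "calibrated"
  out
}

#' Time derivative of a pressure trace
#'
#' Central differences in the interior, one-sided at the endpoints.
#'
#' @param trace tibble with `t_s`, `p_mmHg`.
#' @return tibble `t_s`, `dpdt_mmHg_s`.
#' @export
dpdt <- function(trace) {
  t <- trace$t_s; p <- trace$p_mmHg
  n <- length(p)
  if (n < 3) abort("trace too short for differentiation")
  d <- numeric(n)
  d[2:(n - 1)] <- (p[3:n] - p[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  d[1] <- (p[2] - p[1]) / (t[2] - t[1])
  d[n] <- (p[n] - p[n - 1]) / (t[n] - t[n - 1])
  tibble(t_s = t, dpdt_mmHg_s = d)
}

#' Segment a pressure trace into beats
#'
#' Beat onsets are upward crossings of half the global peak dP/dt, with a
#' 200 ms refractory period; each beat spans one onset to the next.
#'
#' @param trace filtered (and calibrated) tibble with `t_s`, `p_mmHg`.
#' @param refractory_s minimum onset spacing (s).
#' @return tibble `beat`, `t_start_s`, `t_end_s`, `cycle_length_s`.
#' @export
segment_beats <- function(trace, refractory_s = 0.2) {
  d <- dpdt(trace)$dpdt_mmHg_s
  thr <- 0.5 * max(d)
  if (!is.finite(thr) || thr <= 0) abort("no systolic upstrokes found (flat pressure?)")
  up <- which(d[-1] >= thr & d[-length(d)] < thr) + 1L
  if (length(up) > 1) {
    # greedy refractory scan
    sel <- integer(0); last <- -Inf
    for (i in up) {
      if (trace$t_s[i] - last >= refractory_s) { sel <- c(sel, i); last <- trace$t_s[i] }
    }
    up <- sel
  }
  if (length(up) < 3) abort("fewer than 3 beats detected")
  t_on <- trace$t_s[up]
  tibble(
    beat = seq_len(length(up) - 1L),
    t_start_s = t_on[-length(t_on)],
    t_end_s = t_on[-1],
    cycle_length_s = diff(t_on)
  )
}

# Beat index for arbitrary times; NA outside any beat.
beat_index_at <- function(t_s, beats) {
  idx <- findInterval(t_s, beats$t_start_s)
  idx[idx < 1 | t_s >= beats$t_end_s[nrow(beats)]] <- NA_integer_
  idx
}

#' Align an image-derived area series with the pressure trace
#'
#' On a single reference beat, the time at which dP/dt first reaches a
#' quarter of its within-beat peak on the upstroke (`mode = "quarter_dpdt"`,
#' default) or the time of peak dP/dt (`mode = "max_dpdt"`) is matched to the
#' time of the beat's peak (end-diastolic) cavity area; the area peak is
#' refined to sub-frame precision with a parabolic fit through the three
#' frames around the maximum. The single rigid offset returned aligns the
#' whole record: `t_pressure = t_area + offset`.
#'
#' @param area_series tibble with `t_s`, `area_cm2` (frame clock).
#' @param trace filtered, calibrated pressure tibble.
#' @param mode alignment landmark on the pressure side.
#' @param beats beat table from [segment_beats()]; recomputed when `NULL`.
#' @param reference_beat which beat to align on; default the first complete
#'   beat covered by the area series (allowing for lags up to half a cycle).
#' @return list with `offset_s`, `reference_beat`, `t_pressure_s`,
#'   `t_area_peak_s` and `mode`.
#' @export
align_area_pressure <- function(area_series, trace,
                                mode = c("quarter_dpdt", "max_dpdt"),
                                beats = NULL, reference_beat = NULL) {
  mode <- match.arg(mode)
  if (is.null(beats)) beats <- segment_beats(trace)
  if (nrow(beats) < 3) abort("need at least 3 beats for alignment")
  T_med <- median(beats$cycle_length_s)
  if (is.null(reference_beat)) {
    cover <- beats$t_start_s >= (min(area_series$t_s) + T_med / 2) &
      beats$t_end_s <= (max(area_series$t_s) - T_med / 2)
    if (!any(cover)) abort("no beat is fully covered by the area series")
    reference_beat <- beats$beat[which(cover)[1]]
  }
  b <- beats[beats$beat == reference_beat, ]
  d <- dpdt(trace)
  in_beat <- d$t_s >= b$t_start_s - 0.05 & d$t_s < b$t_end_s
  db <- d[in_beat, ]
  pk <- max(db$dpdt_mmHg_s)
  if (mode == "max_dpdt") {
    t_p <- db$t_s[which.max(db$dpdt_mmHg_s)]
  } else {
    thr <- 0.25 * pk
    above <- db$dpdt_mmHg_s >= thr
    ups <- which(above[-1] & !above[-length(above)]) + 1L
    if (length(ups) == 0) ups <- which(above)[1]
    # re-crossings within 50 ms are threshold jitter on one upstroke, not
    # separate upstrokes
    if (length(ups) > 1) {
      ups <- ups[c(TRUE, diff(db$t_s[ups]) > 0.05)]
      if (length(ups) > 1) warn("ambiguous dP/dt upstroke; using the earliest crossing")
    }
    t_p <- db$t_s[ups[1]]
  }
  # peak area nearest the pressure landmark: local maxima within just over
  # half a cycle, the closest in time wins (lags are assumed < half a cycle)
  win <- area_series$t_s >= t_p - 0.55 * T_med & area_series$t_s <= t_p + 0.55 * T_med
  if (!any(win)) abort("area series does not cover the reference beat")
  aw <- area_series[win, ]
  a <- aw$area_cm2
  loc <- which(a >= c(-Inf, a[-length(a)]) & a >= c(a[-1], -Inf))
  loc <- setdiff(loc, c(1L, length(a)))
  j <- if (length(loc) > 0) loc[which.min(abs(aw$t_s[loc] - t_p))] else which.max(a)
  t_a <- aw$t_s[j]
  if (j > 1 && j < nrow(aw)) {
    y0 <- aw$area_cm2[j - 1]; y1 <- aw$area_cm2[j]; y2 <- aw$area_cm2[j + 1]
    den <- y0 - 2 * y1 + y2
    if (abs(den) > 1e-12) {
      delta <- 0.5 * (y0 - y2) / den
      t_a <- t_a + clamp(delta, -1, 1) * median(diff(aw$t_s))
    }
  }
  list(offset_s = t_p - t_a, reference_beat = reference_beat,
       t_pressure_s = t_p, t_area_peak_s = t_a, mode = mode)
}

#' Build synchronized pressure-area loops
#'
#' Resamples each beat onto a uniform grid of `n_interp` instants: pressure is
#' read from the high-rate trace, area is linearly interpolated from the frame
#' series shifted by the alignment offset (`t_pressure = t_area + offset`).
#' Beats not fully covered by the area series are skipped. Obliterated frames
#' (area zero) are retained as zero-area samples.
#'
#' @param area_series tibble with `t_s`, `area_cm2`.
#' @param trace filtered, calibrated pressure tibble.
#' @param offset_s rigid alignment offset from [align_area_pressure()].
#' @param beats beat table; recomputed when `NULL`.
#' @param n_interp samples per beat.
#' @return tibble `beat`, `t_s` (pressure clock), `area_cm2`, `p_mmHg`.
#' @export
build_pa_loops <- function(area_series, trace, offset_s, beats = NULL,
                           n_interp = 50) {
  if (is.null(beats)) beats <- segment_beats(trace)
  a_t <- area_series$t_s + offset_s          # area times in the pressure clock
  t_lo <- min(a_t); t_hi <- max(a_t)
  out <- vector("list", nrow(beats))
  for (i in seq_len(nrow(beats))) {
    b <- beats[i, ]
    if (b$t_start_s < t_lo || b$t_end_s > t_hi) next
    tg <- seq(b$t_start_s, b$t_end_s, length.out = n_interp)
    p <- approx(trace$t_s, trace$p_mmHg, xout = tg)$y
    a <- approx(a_t, area_series$area_cm2, xout = tg)$y
    out[[i]] <- tibble(beat = b$beat, t_s = tg, area_cm2 = a, p_mmHg = p)
  }
  loops <- dplyr::bind_rows(out)
  if (nrow(loops) == 0) abort("no beats fall inside the area-series coverage")
  attr(loops, "offset_s") <- offset_s
  attr(loops, "n_interp") <- n_interp
  loops
}
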