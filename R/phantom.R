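#' Phantom configuration for synthetic VCO studies
#'
#' Builds the configuration object for the synthetic vena-cava-occlusion (VCO)
#' phantom: short-axis image sequences of a bright blood pool inside mid-gray
#' myocardium (ferumoxytol-like contrast), a high-rate LV pressure trace with a
#' pre-acquisition calibration segment and an acquisition-onset noise burst,
#' and (optionally) a conductance-catheter volume record. Every downstream
#' stage of the package can be validated against the ground truth this phantom
#' carries.
#'
#' Geometry and hemodynamics default to values typical of an anesthetized
#' adult sheep: cycle length 0.637 s, frame period 59.2 ms (about 10.8 images
#' per beat), pixel spacing 2.0313 mm, peak LV pressure held near 90 mmHg
#' before occlusion and end-systolic pressure falling 2.26 mmHg per beat
#' during it. The per-level end-systolic pressure-area truths place baseline
#' ES areas near 2.6 / 4.6 / 9.2 cm^2 (apex / mid / base); the apical
#' relationship is quadratic so that the apical cavity obliterates during a
#' 20-beat occlusion, as seen in vivo.
#'
#' @param lv_length_cm apex-to-base LV length (cm).
#' @param level_fractions named fractions of the apex-to-base distance at
#'   which slices are imaged; strictly increasing, in (0, 1).
#' @param espar_truth named list (one entry per level) of quadratic
#'   pressure-on-area coefficients `c(beta2, beta1, beta0)` so that
#'   `P = beta2*A^2 + beta1*A + beta0` at end systole; `beta2 = 0` gives a
#'   linear relationship with slope `beta1` (mmHg/cm^2) and area intercept
#'   `-beta0/beta1` (cm^2).
#' @param heart_period_s cardiac cycle length (s).
#' @param frame_period_ms image frame period (ms); frames are free-running at
#'   this period, so beats contain a non-integer number of frames.
#' @param n_pre_beats beats recorded before image acquisition begins (the
#'   pressure-calibration segment; must cover at least 5 s).
#' @param n_baseline_beats,n_vco_beats imaged beats before and during VCO.
#' @param es_pressure_start_mmHg baseline end-systolic pressure (mmHg).
#' @param es_pressure_decline_mmHg_per_beat per-beat fall of ES pressure
#'   during VCO (mmHg/beat, positive).
#' @param ed_pressure_mmHg diastolic (minimum) pressure (mmHg).
#' @param ed_area_cm2 named per-level end-diastolic areas (cm^2).
#' @param ed_area_decline_cm2_per_beat per-beat ED-area decline during VCO.
#' @param axis_ratio,orientation_deg named per-level cavity ellipse axis
#'   ratios and major-axis orientations (degrees, y-up convention).
#' @param wall_thickness_cm myocardial wall thickness (cm).
#' @param pixel_spacing_mm,image_size_px raster geometry.
#' @param intensity intensities `c(blood, myocardium, background)` on [0, 1].
#' @param noise_sd additive Gaussian image noise (intensity units).
#' @param pressure_fs_Hz pressure sampling rate (Hz, >= 200).
#' @param pressure_noise_sd_mmHg broadband pressure noise (mmHg RMS).
#' @param burst_amplitude_mmHg RMS of the band-limited noise burst that marks
#'   the acquisition window on the raw trace.
#' @param burst_band_Hz frequency band `c(lo, hi)` of the burst (Hz).
#' @param calib_gain,calib_offset_mmHg affine miscalibration applied to the
#'   raw pressure trace (recorded in the ground truth).
#' @param systole_onset_frac,systole_rise_frac,systole_plateau_end_frac,systole_fall_frac
#'   beat-fraction timing of the systolic pressure waveform: upstroke onset,
#'   upstroke duration, end of the late-ejection plateau (the end-systolic
#'   phase) and duration of the isovolumic-relaxation fall. Defaults give an
#'   ED-ES interval of ~0.26 s at the default cycle length.
#' @param valve_kappa valve-plane descent coefficient: the valve-plane
#'   station sits at `L * (1 - valve_kappa * (90 - P)/90)` from the apex.
#' @param alpha_true,cond_offset_ml,cond_noise_sd_ml conductance-catheter
#'   corruption model: measured = truth / alpha_true + offset + noise.
#' @param cond_fs_Hz conductance sampling rate (Hz).
#' @param rng_seed integer seed from which all phantom randomness derives.
#'
#' @return a `phantom_config` list, validated.
#' @export
phantom_config <- function(lv_length_cm = 8,
                           level_fractions = c(apex = 0.25, mid = 0.50, base = 0.75),
                           espar_truth = list(
                             apex = c(beta2 = -5.0, beta1 = 29.2, beta0 = 48.0),
                             mid  = c(beta2 = 0,    beta1 = 20.0, beta0 = 12.02),
                             base = c(beta2 = 0,    beta1 = 10.0, beta0 = 8.39)
                           ),
                           heart_period_s = 0.637,
                           frame_period_ms = 59.2,
                           n_pre_beats = 8,
                           n_baseline_beats = 4,
                           n_vco_beats = 20,
                           es_pressure_start_mmHg = 90,
                           es_pressure_decline_mmHg_per_beat = 2.26,
                           ed_pressure_mmHg = 8,
                           ed_area_cm2 = c(apex = 4.5, mid = 7.5, base = 12.5),
                           ed_area_decline_cm2_per_beat = 0.08,
                           axis_ratio = c(apex = 1.26, mid = 1.16, base = 1.15),
                           orientation_deg = c(apex = 13.7, mid = 51.2, base = 29.9),
                           wall_thickness_cm = 1.1,
                           pixel_spacing_mm = 2.0313,
                           image_size_px = 128,
                           intensity = c(blood = 0.85, myocardium = 0.45, background = 0.10),
                           noise_sd = 0.04,
                           pressure_fs_Hz = 5000,
                           pressure_noise_sd_mmHg = 1.0,
                           burst_amplitude_mmHg = 5.0,
                           burst_band_Hz = c(100, 400),
                           calib_gain = 1.08,
                           calib_offset_mmHg = -4,
                           systole_onset_frac = 0.05,
                           systole_rise_frac = 0.20,
                           systole_plateau_end_frac = 0.47,
                           systole_fall_frac = 0.18,
                           valve_kappa = 0.1,
                           alpha_true = 0.39,
                           cond_offset_ml = 30,
                           cond_noise_sd_ml = 0.8,
                           cond_fs_Hz = 250,
                           rng_seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- c("phantom_config", "list")
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  lf <- cfg$level_fractions
  if (length(lf) < 1 || any(lf <= 0) || any(lf >= 1) || any(diff(lf) <= 0)) {
    abort("`level_fractions` must be strictly increasing and inside (0, 1)")
  }
  if (is.null(names(lf)) || any(!nzchar(names(lf)))) {
    abort("`level_fractions` must be named")
  }
  for (nm in names(lf)) {
    if (is.null(cfg$espar_truth[[nm]])) abort(sprintf("espar_truth missing level '%s'", nm))
    if (is.na(cfg$ed_area_cm2[nm])) abort(sprintf("ed_area_cm2 missing level '%s'", nm))
  }
  fpb <- cfg$heart_period_s * 1000 / cfg$frame_period_ms
  if (fpb < 6) abort("fewer than 6 frames per beat")
  if (cfg$es_pressure_decline_mmHg_per_beat <= 0) abort("ES pressure decline must be > 0")
  if (cfg$pressure_fs_Hz < 200) abort("pressure_fs_Hz must be >= 200")
  for (nm in c("lv_length_cm", "heart_period_s", "frame_period_ms", "wall_thickness_cm",
               "pixel_spacing_mm", "image_size_px", "heart_period_s")) {
    stopifnot_scalar_pos(cfg[[nm]], nm)
  }
  if (cfg$n_pre_beats * cfg$heart_period_s < 5) {
    abort("pre-acquisition segment must cover at least 5 s")
  }
  sched <- phantom_beat_schedule(cfg)
  for (nm in names(lf)) {
    a_es <- espar_truth_area(cfg$espar_truth[[nm]], sched$p_es)
    a_ed <- phantom_ed_areas(cfg, nm, sched)
    if (any(a_ed <= a_es)) {
      abort(sprintf("configuration drives ED area below ES area at level '%s'", nm))
    }
  }
  invisible(cfg)
}

# ---- truth end-systolic pressure-area relationship -------------------------

# Area on the physical (rising) branch of P = b2 A^2 + b1 A + b0, clamped >= 0.
espar_truth_area <- function(coefs, p) {
  b2 <- unname(coefs[1]); b1 <- unname(coefs[2]); b0 <- unname(coefs[3])
  if (b2 == 0) {
    a <- (p - b0) / b1
  } else {
    disc <- b1^2 - 4 * b2 * (b0 - p)
    if (any(disc < 0)) {
      abort("truth ESPAR has no real area at a requested pressure (pressure above the curve's maximum)")
    }
    # branch with dP/dA = b1 + 2 b2 A > 0
    a <- (-b1 + sqrt(disc)) / (2 * b2)
    bad <- b1 + 2 * b2 * a <= 0
    if (any(bad)) a[bad] <- (-b1 - sqrt(disc[bad])) / (2 * b2)
  }
  pmax(a, 0)
}

# ---- beat schedule ---------------------------------------------------------

# Per-beat truth: phase of the experiment and end-systolic pressure.
phantom_beat_schedule <- function(cfg) {
  n_pre <- cfg$n_pre_beats; n_base <- cfg$n_baseline_beats; n_vco <- cfg$n_vco_beats
  n <- n_pre + n_base + n_vco
  beat <- seq_len(n) - 1L
  stage <- rep(c("pre", "baseline", "vco"), c(n_pre, n_base, n_vco))
  vco_idx <- pmax(beat - (n_pre + n_base) + 1L, 0L)
  p_es <- cfg$es_pressure_start_mmHg - cfg$es_pressure_decline_mmHg_per_beat * vco_idx
  tibble(beat = beat, stage = stage, vco_beat = vco_idx, p_es = p_es)
}

phantom_ed_areas <- function(cfg, level, sched) {
  pmax(cfg$ed_area_cm2[[level]] - cfg$ed_area_decline_cm2_per_beat * sched$vco_beat, 0)
}

# Phase (beat fraction) of end-diastole: where dP/dt first reaches 25% of its
# beat maximum on the half-cosine systolic upstroke.
phantom_ed_phase <- function(cfg) {
  cfg$systole_onset_frac + cfg$systole_rise_frac * asin(0.25) / pi
}

phantom_es_phase <- function(cfg) cfg$systole_plateau_end_frac

# Continuous pressure model: half-cosine upstroke, late-ejection plateau at
# the beat's end-systolic pressure, then a fast half-cosine (isovolumic
# relaxation) return to the diastolic minimum. End systole (minimum cavity
# area, maximal elastance) sits at the end of the plateau, as in vivo, so the
# pairing of nadir area with near-peak pressure is robust to frame-scale
# timing shifts.
phantom_pressure_at <- function(t_s, cfg, sched) {
  T <- cfg$heart_period_s
  b <- pmin(pmax(floor(t_s / T), 0), nrow(sched) - 1L)
  phi <- t_s / T - b
  on <- cfg$systole_onset_frac
  r <- cfg$systole_rise_frac
  pe <- cfg$systole_plateau_end_frac
  f <- cfg$systole_fall_frac
  h <- numeric(length(phi))
  rise <- phi >= on & phi < on + r
  h[rise] <- 0.5 * (1 - cos(pi * (phi[rise] - on) / r))
  h[phi >= on + r & phi < pe] <- 1
  fall <- phi >= pe & phi < pe + f
  h[fall] <- 0.5 * (1 + cos(pi * (phi[fall] - pe) / f))
  p_es <- sched$p_es[b + 1L]
  cfg$ed_pressure_mmHg + (p_es - cfg$ed_pressure_mmHg) * h
}

# Event-based cavity-area model: half-cosine interpolation between alternating
# ED / ES events, with per-beat ED and ES area truths.
phantom_area_events <- function(cfg, level, sched) {
  T <- cfg$heart_period_s
  phi_ed <- phantom_ed_phase(cfg); phi_es <- phantom_es_phase(cfg)
  a_es <- espar_truth_area(cfg$espar_truth[[level]], sched$p_es)
  a_ed <- phantom_ed_areas(cfg, level, sched)
  n <- nrow(sched)
  t_ev <- c((phi_es - 1) * T,
            as.vector(rbind((sched$beat + phi_ed) * T, (sched$beat + phi_es) * T)),
            (n + phi_ed) * T)
  a_ev <- c(a_es[1], as.vector(rbind(a_ed, a_es)), a_ed[n])
  list(t = t_ev, a = a_ev)
}

phantom_area_at <- function(t_s, events) {
  i <- findInterval(t_s, events$t, all.inside = TRUE)
  u <- (t_s - events$t[i]) / (events$t[i + 1] - events$t[i])
  events$a[i] + (events$a[i + 1] - events$a[i]) * (1 - cos(pi * u)) / 2
}

# ---- rasterization ---------------------------------------------------------

# Fractional pixel coverage of an ellipse, 4x4 supersampled, restricted to the
# ellipse's bounding box. Center (cx, cy) in cm, y-up physical frame with
# x = col0 * s and y = -row0 * s, s = pixel spacing in cm.
ellipse_coverage <- function(nrow_px, ncol_px, s_cm, cx, cy, a, b, theta_deg, ss = 4L) {
  cov <- matrix(0, nrow_px, ncol_px)
  if (a <= 0 || b <= 0) return(cov)
  r_max <- max(a, b)
  col_rng <- clamp(floor((cx - r_max) / s_cm):ceiling((cx + r_max) / s_cm), 0, ncol_px - 1)
  row_rng <- clamp(floor((-cy - r_max) / s_cm):ceiling((-cy + r_max) / s_cm), 0, nrow_px - 1)
  col_rng <- unique(col_rng); row_rng <- unique(row_rng)
  th <- theta_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  off <- ((seq_len(ss) - 0.5) / ss - 0.5) * s_cm
  sub <- expand.grid(dx = off, dy = off)
  px <- expand.grid(row0 = row_rng, col0 = col_rng)
  x0 <- px$col0 * s_cm; y0 <- -px$row0 * s_cm
  acc <- numeric(nrow(px))
  for (k in seq_len(nrow(sub))) {
    x <- x0 + sub$dx[k] - cx; y <- y0 + sub$dy[k] - cy
    xr <- ct * x + st * y; yr <- -st * x + ct * y
    acc <- acc + ((xr / a)^2 + (yr / b)^2 <= 1)
  }
  cov[cbind(px$row0 + 1L, px$col0 + 1L)] <- acc / nrow(sub)
  cov
}

# ---- image sequence generator ----------------------------------------------

#' Generate one synthetic short-axis VCO image sequence with ground truth
#'
#' Renders free-running short-axis frames of an elliptical LV cavity whose
#' end-systolic area follows the configured truth pressure-area relationship
#' at each beat's end-systolic pressure (clamped at zero once the cavity
#' obliterates). Frames cover the acquisition window only; the pressure trace
#' from [generate_pressure_trace()] additionally covers the pre-acquisition
#' calibration segment.
#'
#' @param level_fraction slice position as a fraction of apex-to-base length;
#'   must match one of `config$level_fractions`.
#' @param config a [phantom_config()].
#' @return list with components `sequence` (class `rt_sequence`: `frames`
#'   array \[row, col, frame\], `t_s`, spacing/period metadata and the RV
#'   insertion landmark) and `truth` (class `phantom_truth`: per-frame tibble,
#'   truth masks, per-beat tibble and the truth ESPAR coefficients).
#' @export
generate_vco_sequence <- function(level_fraction, config = phantom_config()) {
  validate_phantom_config(config)
  idx <- which(abs(config$level_fractions - level_fraction) < 1e-9)
  if (length(idx) != 1L) abort("level_fraction must match one entry of config$level_fractions")
  level <- names(config$level_fractions)[idx]

  sched <- phantom_beat_schedule(config)
  events <- phantom_area_events(config, level, sched)
  T <- config$heart_period_s
  dt <- config$frame_period_ms / 1000
  t_acq0 <- config$n_pre_beats * T
  t_end <- nrow(sched) * T
  n_frames <- floor((t_end - t_acq0) / dt)
  t_s <- t_acq0 + (seq_len(n_frames) - 1L) * dt

  n_px <- config$image_size_px
  s_cm <- config$pixel_spacing_mm / 10
  ctr_cm <- c(x = (n_px / 2 - 0.5) * s_cm, y = -(n_px / 2 - 0.5) * s_cm)
  ratio <- config$axis_ratio[[level]]
  theta <- config$orientation_deg[[level]]
  wall <- config$wall_thickness_cm
  ints <- config$intensity
  half_px_area <- 0.5 * s_cm^2

  area <- phantom_area_at(t_s, events)
  beat <- pmin(floor(t_s / T), nrow(sched) - 1L)
  frames <- array(0, dim = c(n_px, n_px, n_frames))
  masks <- vector("list", n_frames)
  a_cm <- sqrt(area * ratio / pi)
  b_cm <- sqrt(area / (pi * ratio))

  frame_tbl <- tibble(
    frame = seq_len(n_frames), t_s = t_s, beat = beat,
    area_cm2 = area, a_cm = a_cm, b_cm = b_cm,
    theta_deg = theta, collapsed = area < half_px_area
  )

  with_seed(config$rng_seed + idx, {
    for (k in seq_len(n_frames)) {
      cov_epi <- ellipse_coverage(n_px, n_px, s_cm, ctr_cm["x"], ctr_cm["y"],
                                  a_cm[k] + wall, b_cm[k] + wall, theta)
      if (area[k] >= half_px_area) {
        cov_cav <- ellipse_coverage(n_px, n_px, s_cm, ctr_cm["x"], ctr_cm["y"],
                                    a_cm[k], b_cm[k], theta)
      } else {
        cov_cav <- matrix(0, n_px, n_px)
      }
      img <- ints[["background"]] * (1 - cov_epi) +
        ints[["myocardium"]] * (cov_epi - cov_cav) +
        ints[["blood"]] * cov_cav
      if (config$noise_sd > 0) img <- img + rnorm(length(img), sd = config$noise_sd)
      frames[, , k] <- img
      masks[[k]] <- cov_cav >= 0.5
    }
  })

  # RV insertion landmark: fixed pixel on the anterior epicardial margin.
  psi <- (theta + 25) * pi / 180
  rv_xy <- c(ctr_cm["x"] + 3.5 * cos(psi), ctr_cm["y"] + 3.5 * sin(psi))
  rv_px <- c(row = unname(-rv_xy[2] / s_cm), col = unname(rv_xy[1] / s_cm))

  beats <- sched |>
    mutate(
      a_es = espar_truth_area(config$espar_truth[[level]], .data$p_es),
      a_ed = phantom_ed_areas(config, level, sched),
      t_ed = (.data$beat + phantom_ed_phase(config)) * T,
      t_es = (.data$beat + phantom_es_phase(config)) * T
    )

  sequence <- structure(list(
    frames = frames, t_s = t_s,
    pixel_spacing_mm = config$pixel_spacing_mm,
    frame_period_ms = config$frame_period_ms,
    rv_insertion_px = rv_px,
    level = level, level_fraction = level_fraction,
    acquisition_start_s = t_acq0
  ), class = "rt_sequence")

  truth <- structure(list(
    frames = frame_tbl, masks = masks, beats = beats,
    espar = config$espar_truth[[level]],
    level = level, pixel_spacing_mm = config$pixel_spacing_mm,
    obliteration_threshold_cm2 = 0.25
  ), class = "phantom_truth")

  list(sequence = sequence, truth = truth)
}

# ---- pressure trace generator ----------------------------------------------

#' Generate a raw and truth LV pressure trace for one VCO run
#'
#' The truth trace is the noise-free continuous pressure model sampled at
#' `pressure_fs_Hz`. The raw trace adds broadband Gaussian noise, a
#' band-limited noise burst spanning the image-acquisition window (the marker
#' used to localize acquisition on the unfiltered trace), and an affine
#' miscalibration whose gain and offset are recorded in the returned metadata.
#'
#' @param config a [phantom_config()].
#' @param seed_offset integer added to `config$rng_seed` so that each imaging
#'   level can receive an independent pressure recording.
#' @return list with `raw` and `truth` tibbles (`t_s`, `p_mmHg`) and `meta`
#'   (sampling rate, true gain/offset, acquisition window, beat schedule).
#' @export
generate_pressure_trace <- function(config = phantom_config(), seed_offset = 0L) {
  validate_phantom_config(config)
  sched <- phantom_beat_schedule(config)
  fs <- config$pressure_fs_Hz
  T <- config$heart_period_s
  t_end <- nrow(sched) * T
  t_s <- seq(0, t_end - 1 / fs, by = 1 / fs)
  truth_p <- phantom_pressure_at(t_s, config, sched)
  acq <- c(start_s = config$n_pre_beats * T, end_s = t_end)

  raw_p <- with_seed(config$rng_seed + 7919L + seed_offset, {
    p <- config$calib_gain * truth_p + config$calib_offset_mmHg
    if (config$pressure_noise_sd_mmHg > 0) {
      p <- p + rnorm(length(p), sd = config$pressure_noise_sd_mmHg)
    }
    if (config$burst_amplitude_mmHg > 0) {
      bf <- signal::butter(4, config$burst_band_Hz / (fs / 2), type = "pass")
      burst <- signal::filtfilt(bf, rnorm(length(p)))
      in_acq <- t_s >= acq["start_s"] & t_s <= acq["end_s"]
      burst_rms <- sqrt(mean(burst[in_acq]^2))
      p <- p + config$burst_amplitude_mmHg / burst_rms * burst * in_acq
    }
    p
  })

  list(
    raw = tibble(t_s = t_s, p_mmHg = raw_p),
    truth = tibble(t_s = t_s, p_mmHg = truth_p),
    meta = list(
      fs_Hz = fs, gain = config$calib_gain, offset_mmHg = config$calib_offset_mmHg,
      acquisition_start_s = unname(acq["start_s"]),
      acquisition_end_s = unname(acq["end_s"]),
      beats = sched,
      ed_pressure_mmHg = config$ed_pressure_mmHg,
      peak_pressure_mmHg = config$es_pressure_start_mmHg
    )
  )
}

# ---- multi-level study -----------------------------------------------------

#' Generate a complete multi-level phantom study
#'
#' One image sequence plus an independent pressure recording per configured
#' level (levels are acquired during separate occlusions, as in the imaging
#' protocol), together with the truth end-systolic pressure-volume curve
#' computed from the truth areas with the same trapezoidal station scheme the
#' fitting pipeline uses.
#'
#' @inheritParams generate_pressure_trace
#' @param pressure_grid_mmHg grid on which the truth ESPVR is tabulated.
#' @return an `rt_study` list: `levels` (each with `sequence`, `truth`,
#'   `pressure`), `truth_espvr` (an `espvr` object) and the `config`.
#' @export
generate_multilevel_study <- function(config = phantom_config(),
                                      pressure_grid_mmHg = seq(50, 90, by = 5)) {
  validate_phantom_config(config)
  if (length(config$level_fractions) < 3) abort("a study needs at least 3 levels")
  levels <- names(config$level_fractions)
  out <- vector("list", length(levels)); names(out) <- levels
  for (i in seq_along(levels)) {
    g <- generate_vco_sequence(config$level_fractions[[i]], config)
    g$pressure <- generate_pressure_trace(config, seed_offset = 131L * i)
    out[[i]] <- g
  }
  truth_espvr <- build_espvr(
    setNames(lapply(levels, function(l) config$espar_truth[[l]]), levels),
    lv_length_cm = config$lv_length_cm,
    level_fractions = config$level_fractions,
    grid_mmHg = pressure_grid_mmHg,
    valve_kappa = config$valve_kappa
  )
  structure(list(levels = out, truth_espvr = truth_espvr, config = config),
            class = "rt_study")
}

# ---- conductance record ----------------------------------------------------

#' Generate a synthetic conductance-catheter record with ground truth
#'
#' The truth volume trace integrates the instantaneous per-level truth areas
#' with the same trapezoidal station scheme used for the ESPVR; the measured
#' signal is corrupted with the inverse of the two-point calibration model:
#' `measured = truth / alpha_true + offset_true + noise`.
#'
#' @inheritParams generate_pressure_trace
#' @return list with `record` (tibble `t_s`, `v_ml` (measured), `p_mmHg`) and
#'   `truth` (true volume trace, `alpha_true`, `offset_true`, cine-equivalent
#'   baseline ED/ES volumes and the beat schedule).
#' @export
generate_conductance_record <- function(config = phantom_config(), seed_offset = 0L) {
  validate_phantom_config(config)
  sched <- phantom_beat_schedule(config)
  fs <- config$cond_fs_Hz
  T <- config$heart_period_s
  t_s <- seq(0, nrow(sched) * T - 1 / fs, by = 1 / fs)
  p <- phantom_pressure_at(t_s, config, sched)

  levels <- names(config$level_fractions)
  areas <- sapply(levels, function(l) {
    phantom_area_at(t_s, phantom_area_events(config, l, sched))
  })
  v_truth <- vapply(seq_along(t_s), function(i) {
    lv_station_volume(setNames(areas[i, ], levels),
                      lv_length_cm = config$lv_length_cm,
                      level_fractions = config$level_fractions,
                      pressure_mmHg = p[i],
                      valve_kappa = config$valve_kappa)
  }, numeric(1))

  rec <- with_seed(config$rng_seed + 24251L + seed_offset, {
    v_meas <- v_truth / config$alpha_true + config$cond_offset_ml +
      rnorm(length(v_truth), sd = config$cond_noise_sd_ml)
    p_meas <- p + rnorm(length(p), sd = config$pressure_noise_sd_mmHg / 5)
    tibble(t_s = t_s, v_ml = v_meas, p_mmHg = p_meas)
  })

  baseline <- t_s < (config$n_pre_beats + config$n_baseline_beats) * T
  truth <- list(
    t_s = t_s, v_ml = v_truth, p_mmHg = p,
    alpha_true = config$alpha_true, offset_true = config$cond_offset_ml,
    cine_ed_ml = max(v_truth[baseline]), cine_es_ml = min(v_truth[baseline]),
    beats = sched, fs_Hz = fs,
    baseline_end_s = (config$n_pre_beats + config$n_baseline_beats) * T
  )
  list(record = rec, truth = truth)
}
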