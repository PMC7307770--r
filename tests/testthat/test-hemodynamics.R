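test_that("zero-phase filtering has unity DC gain and strong stopband attenuation", {
  fs <- 1000
  t <- seq(0, 4, by = 1 / fs)
  dc <- tibble::tibble(t_s = t, p_mmHg = rep(70, length(t)))
  expect_equal(filter_pressure(dc, 30)$p_mmHg, dc$p_mmHg, tolerance = 1e-6)
  tone <- tibble::tibble(t_s = t, p_mmHg = sin(2 * pi * 150 * t))  # 5 x cutoff
  out <- filter_pressure(tone, 30)
  mid <- t > 1 & t < 3
  atten_db <- 20 * log10(max(abs(out$p_mmHg[mid])) / 1)
  expect_lt(atten_db, -40)
  expect_error(filter_pressure(dc, 600), "Nyquist")
  jag <- tibble::tibble(t_s = c(0, 0.1, 0.15, 0.4), p_mmHg = 1:4)
  expect_error(filter_pressure(jag, 1), "uniform")
})

test_that("filtering recovers the truth trace from the corrupted phantom recording", {
  cfg <- phantom_config(calib_gain = 1, calib_offset_mmHg = 0)
  pt <- generate_pressure_trace(cfg)
  rmse_raw <- sqrt(mean((pt$raw$p_mmHg - pt$truth$p_mmHg)^2))
  filt <- filter_pressure(pt$raw, 30)
  rmse_filt <- sqrt(mean((filt$p_mmHg - pt$truth$p_mmHg)^2))
  expect_gte(rmse_raw / rmse_filt, 5)
})

test_that("the acquisition window is localized from the burst to within 100 ms", {
  cfg <- phantom_config()
  pt <- generate_pressure_trace(cfg)
  w <- detect_acquisition_window(pt$raw)
  expect_lt(abs(w[["start_s"]] - pt$meta$acquisition_start_s), 0.1)
  expect_lt(abs(w[["end_s"]] - pt$meta$acquisition_end_s), 0.1)
  # burst-free trace and degenerate threshold both error
  quiet <- generate_pressure_trace(phantom_config(burst_amplitude_mmHg = 0))
  expect_error(detect_acquisition_window(quiet$raw), "manual")
  expect_error(detect_acquisition_window(pt$raw, k = Inf), "manual")
})

test_that("pressure calibration inverts a known affine corruption", {
  cfg <- phantom_config(calib_gain = 1.2, calib_offset_mmHg = -7,
                        pressure_noise_sd_mmHg = 0, burst_amplitude_mmHg = 0)
  pt <- generate_pressure_trace(cfg)
  ref <- c(ed = cfg$ed_pressure_mmHg, peak = cfg$es_pressure_start_mmHg)
  cal <- calibrate_pressure(pt$raw, c(0, pt$meta$acquisition_start_s), ref)
  map <- attr(cal, "calibration")
  expect_equal(map$gain * cfg$calib_gain, 1, tolerance = 0.01)
  expect_equal(cal$p_mmHg, pt$truth$p_mmHg, tolerance = 0.01)

  # offset-only corruption recovers unit gain
  cfg2 <- phantom_config(calib_gain = 1, calib_offset_mmHg = -5,
                         pressure_noise_sd_mmHg = 0, burst_amplitude_mmHg = 0)
  pt2 <- generate_pressure_trace(cfg2)
  cal2 <- calibrate_pressure(pt2$raw, c(0, pt2$meta$acquisition_start_s), ref)
  expect_equal(attr(cal2, "calibration")$gain, 1, tolerance = 1e-6)

  # identity: calibrating against the observed extremes changes nothing
  beats <- segment_beats(pt2$truth)
  obs <- calibrate_pressure(pt2$truth, c(0, pt2$meta$acquisition_start_s),
                            c(ed = cfg2$ed_pressure_mmHg, peak = 90))
  expect_equal(obs$p_mmHg, pt2$truth$p_mmHg, tolerance = 1e-9)
})

test_that("filtering and affine calibration commute", {
  cfg <- fast_cfg()
  pt <- generate_pressure_trace(cfg)
  f_then_a <- 1.1 * filter_pressure(pt$raw, 30)$p_mmHg - 4
  a_then_f <- filter_pressure(
    tibble::tibble(t_s = pt$raw$t_s, p_mmHg = 1.1 * pt$raw$p_mmHg - 4), 30)$p_mmHg
  expect_equal(f_then_a, a_then_f, tolerance = 1e-6)
})

test_that("the pressure derivative matches closed forms", {
  fs <- 1000
  t <- seq(0, 2, by = 1 / fs)
  ramp <- dpdt(tibble::tibble(t_s = t, p_mmHg = 3.5 * t))
  expect_equal(ramp$dpdt_mmHg_s[2:(length(t) - 1)],
               rep(3.5, length(t) - 2), tolerance = 1e-9)
  expect_equal(dpdt(tibble::tibble(t_s = t, p_mmHg = rep(7, length(t))))$dpdt_mmHg_s,
               rep(0, length(t)))
  w <- 2 * pi * 5
  sine <- dpdt(tibble::tibble(t_s = t, p_mmHg = 2 * sin(w * t)))
  expect_equal(max(sine$dpdt_mmHg_s), 2 * w, tolerance = 0.01)
})

test_that("beat segmentation recovers the phantom cycle length", {
  cfg <- phantom_config()
  pt <- generate_pressure_trace(cfg)
  tr <- filter_pressure(pt$raw, 30)
  beats <- segment_beats(tr)
  expect_lt(abs(median(beats$cycle_length_s) - cfg$heart_period_s),
            cfg$frame_period_ms / 1000)
  expect_equal(nrow(beats) + 1L,
               cfg$n_pre_beats + cfg$n_baseline_beats + cfg$n_vco_beats,
               tolerance = 1)
  one_beat <- pt$truth[pt$truth$t_s < 0.64, ]
  expect_error(segment_beats(one_beat), "beats")
  flat <- tibble::tibble(t_s = pt$truth$t_s, p_mmHg = 50)
  expect_error(segment_beats(flat), "flat|beats")
})

test_that("imposed alignment lags are recovered to sub-frame accuracy", {
  cfg <- phantom_config()
  g <- generate_vco_sequence(0.50, cfg)
  pt <- generate_pressure_trace(cfg)
  tr <- calibrate_pressure(filter_pressure(pt$raw, 30),
                           c(0, pt$meta$acquisition_start_s),
                           c(ed = cfg$ed_pressure_mmHg, peak = 90))
  half_frame <- cfg$frame_period_ms / 2000
  for (lag in c(-0.3, -0.12, 0, 0.12, 0.3)) {
    ser <- g$truth$frames[, c("t_s", "area_cm2")]
    ser$t_s <- ser$t_s - lag
    al <- suppressWarnings(align_area_pressure(ser, tr))
    expect_lt(abs(al$offset_s - lag), half_frame)
  }
})

test_that("loops carry the truth end-systolic pressure and respect coverage bookkeeping", {
  cfg <- phantom_config()
  g <- generate_vco_sequence(0.50, cfg)
  pt <- generate_pressure_trace(cfg)
  tr <- calibrate_pressure(filter_pressure(pt$raw, 30),
                           c(0, pt$meta$acquisition_start_s),
                           c(ed = cfg$ed_pressure_mmHg, peak = 90))
  beats <- segment_beats(tr)
  ser <- g$truth$frames[, c("t_s", "area_cm2")]
  al <- suppressWarnings(align_area_pressure(ser, tr, beats = beats))
  loops <- build_pa_loops(ser, tr, al$offset_s, beats = beats)
  # per-beat loop maxima match the truth ES pressure schedule within 1 mmHg
  pk <- loops |> dplyr::group_by(beat) |>
    dplyr::summarise(pmax = max(p_mmHg), .groups = "drop")
  # beat numbering from segment_beats is global: its beat i spans model beat
  # i - 1 (the first onset falls in model beat 0)
  sched <- pt$meta$beats
  truth_pk <- sched$p_es[match(pk$beat - 1, sched$beat)]
  expect_lt(max(abs(pk$pmax - truth_pk)), 1)
  # loop count equals complete beats inside the area coverage
  a_t <- ser$t_s + al$offset_s
  n_expected <- sum(beats$t_start_s >= min(a_t) & beats$t_end_s <= max(a_t))
  expect_equal(length(unique(loops$beat)), n_expected)
  # interpolation preserves the per-beat extremes up to one interpolation
  # step's worth of curvature error (grid step ~13 ms on a ~0.6 s beat)
  b1 <- loops[loops$beat == unique(loops$beat)[2], ]
  in_b <- a_t >= min(b1$t_s) & a_t <= max(b1$t_s)
  expect_lt(abs(max(b1$area_cm2) - max(ser$area_cm2[in_b])), 0.05)
  expect_lte(max(b1$area_cm2), max(ser$area_cm2[in_b]) + 1e-9)
  # a constant area series degenerates to a vertical segment
  flat <- tibble::tibble(t_s = ser$t_s, area_cm2 = 5)
  lf <- build_pa_loops(flat, tr, 0, beats = beats)
  expect_equal(diff(range(lf$area_cm2)), 0)
})
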