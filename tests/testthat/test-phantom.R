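test_that("identical seed and configuration reproduce every product exactly", {
  cfg <- fast_cfg(rng_seed = 11)
  g1 <- generate_vco_sequence(0.50, cfg)
  g2 <- generate_vco_sequence(0.50, cfg)
  expect_identical(g1$sequence$frames, g2$sequence$frames)
  expect_identical(g1$truth$masks, g2$truth$masks)
  p1 <- generate_pressure_trace(cfg)
  p2 <- generate_pressure_trace(cfg)
  expect_identical(p1$raw$p_mmHg, p2$raw$p_mmHg)
  c1 <- generate_conductance_record(cfg)
  c2 <- generate_conductance_record(cfg)
  expect_identical(c1$record, c2$record)
  g3 <- generate_vco_sequence(0.50, fast_cfg(rng_seed = 12))
  expect_false(identical(g1$sequence$frames, g3$sequence$frames))
})

test_that("rasterized truth masks track the analytic ellipse area", {
  s <- 0.20313
  # generic placements: threshold-at-half-coverage is unbiased but carries
  # O(1 px) placement-phase fluctuation at 2 mm spacing
  set.seed(5)
  errs <- sapply(1:8, function(i) {
    m <- raster_ellipse(1.0, 0.8, runif(1, 0, 180),
                        cx = runif(1, 10, 15), cy = -runif(1, 10, 15), ss = 4L)
    (sum(m) * s^2 - pi * 1.0 * 0.8) / s^2
  })
  expect_lt(abs(mean(errs)), 1)     # unbiased to within one pixel
  expect_lt(max(abs(errs)), 3)      # per-instance rasterization phase error
})

test_that("end-systolic pressure declines by the configured amount per VCO beat and truth areas obey the ESPAR", {
  cfg <- phantom_config()
  g <- generate_vco_sequence(0.25, cfg)
  b <- g$truth$beats
  vco <- b[b$stage == "vco", ]
  expect_equal(diff(vco$p_es),
               rep(-cfg$es_pressure_decline_mmHg_per_beat, nrow(vco) - 1))
  expect_true(all(diff(vco$p_es) < 0))
  # conservation: truth ES area is exactly the ESPAR inverse, clamped at 0
  co <- cfg$espar_truth$apex
  open <- vco$a_es > 0
  expect_equal(co[["beta2"]] * vco$a_es[open]^2 + co[["beta1"]] * vco$a_es[open] +
                 co[["beta0"]], vco$p_es[open], tolerance = 1e-12)
  expect_true(all(vco$a_es >= 0))
})

test_that("the default apex level obliterates during the occlusion", {
  g <- generate_vco_sequence(0.25, phantom_config())
  expect_true(any(g$truth$beats$a_es <= 0.25))
  # and rendered frames follow: some frames have (near-)empty truth masks
  expect_true(any(g$truth$frames$area_cm2 <= 0.25))
})

test_that("raw pressure equals truth when every corruption is disabled", {
  cfg <- fast_cfg(pressure_noise_sd_mmHg = 0, burst_amplitude_mmHg = 0,
                  calib_gain = 1, calib_offset_mmHg = 0)
  pt <- generate_pressure_trace(cfg)
  expect_equal(pt$raw$p_mmHg, pt$truth$p_mmHg, tolerance = 1e-12)
})

test_that("the acquisition-window burst dominates the band-limited RMS", {
  cfg <- phantom_config(pressure_noise_sd_mmHg = 0.5,
                        burst_amplitude_mmHg = 5)
  pt <- generate_pressure_trace(cfg)
  fs <- pt$meta$fs_Hz
  bf <- signal::butter(4, 80 / (fs / 2), type = "high")
  hp <- signal::filtfilt(bf, pt$raw$p_mmHg)
  inside <- pt$raw$t_s > pt$meta$acquisition_start_s + 0.5 &
    pt$raw$t_s < pt$meta$acquisition_end_s - 0.5
  outside <- pt$raw$t_s > 0.5 & pt$raw$t_s < pt$meta$acquisition_start_s - 0.5
  expect_gte(sqrt(mean(hp[inside]^2)) / sqrt(mean(hp[outside]^2)), 5)
})

test_that("configurations that drive ED area below ES area are rejected", {
  expect_error(fast_cfg(ed_area_cm2 = c(apex = 1.0, mid = 2.0, base = 4.0)),
               "ED area below ES area")
  expect_error(fast_cfg(level_fractions = c(apex = 0.5, mid = 0.25, base = 0.75)),
               "strictly increasing")
  expect_error(fast_cfg(es_pressure_decline_mmHg_per_beat = -1), "decline")
  expect_error(fast_cfg(pressure_fs_Hz = 100), "pressure_fs_Hz")
})

test_that("truth ESPVR from the study uses the trapezoidal station scheme", {
  # all-linear ESPAR truths, no collapse, fixed valve plane: volumes are an
  # exactly linear function of pressure
  cfg <- fast_cfg(
    espar_truth = list(apex = c(beta2 = 0, beta1 = 30, beta0 = 10),
                       mid = c(beta2 = 0, beta1 = 20, beta0 = 12),
                       base = c(beta2 = 0, beta1 = 10, beta0 = 8)),
    valve_kappa = 0)
  st <- generate_multilevel_study(cfg)
  grid <- st$truth_espvr$grid
  # definitional check at 90 mmHg
  a90 <- sapply(names(cfg$level_fractions), function(l) {
    rtpvr:::espar_truth_area(cfg$espar_truth[[l]], 90)
  })
  v90 <- rtpvr:::lv_station_volume(a90, cfg$lv_length_cm, cfg$level_fractions,
                                   90, valve_kappa = 0)
  expect_equal(grid$v_ml[grid$p_mmHg == 90], v90, tolerance = 1e-12)
  qfit <- lm(p_mmHg ~ v_ml + I(v_ml^2), data = grid)
  expect_lt(abs(coef(qfit)[3]), 1e-9)

  # a level that clamps to zero inside the grid bends the truth ESPVR
  cfg2 <- fast_cfg(
    espar_truth = list(apex = c(beta2 = 0, beta1 = 28, beta0 = 60),
                       mid = c(beta2 = 0, beta1 = 20, beta0 = 12),
                       base = c(beta2 = 0, beta1 = 10, beta0 = 8)),
    valve_kappa = 0)
  st2 <- generate_multilevel_study(cfg2)
  qfit2 <- lm(p_mmHg ~ v_ml + I(v_ml^2), data = st2$truth_espvr$grid)
  expect_gt(abs(coef(qfit2)[3]), 1e-6)
})

test_that("conductance corruption model is the inverse of the calibration", {
  cfg0 <- fast_cfg(alpha_true = 1, cond_offset_ml = 0, cond_noise_sd_ml = 0,
                   pressure_noise_sd_mmHg = 0)
  c0 <- generate_conductance_record(cfg0)
  expect_equal(c0$record$v_ml, c0$truth$v_ml, tolerance = 1e-12)

  cfg2 <- fast_cfg(alpha_true = 2, cond_offset_ml = 10, cond_noise_sd_ml = 0)
  c2 <- generate_conductance_record(cfg2)
  base <- c2$record$t_s <= c2$truth$baseline_end_s
  meas_swing <- max(c2$record$v_ml[base]) - min(c2$record$v_ml[base])
  truth_swing <- max(c2$truth$v_ml[base]) - min(c2$truth$v_ml[base])
  expect_equal(meas_swing, truth_swing / 2, tolerance = 1e-12)

  # gain recovery on the noiseless record
  rec <- calibrate_conductance(c2$record, c2$truth$cine_ed_ml, c2$truth$cine_es_ml,
                               baseline_window = c(0, c2$truth$baseline_end_s),
                               volume_cutoff_Hz = NULL)
  expect_equal(attr(rec, "alpha"), 2, tolerance = 1e-9)
})
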