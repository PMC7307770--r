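test_that("the maximal-elastance iteration recovers a known linear ESPAR exactly", {
  loops <- make_linear_loops(slope = 10, a0 = 1)
  es <- find_es_points(loops, collapse_threshold = -Inf)
  expect_true(es$converged)
  expect_equal(es$slope, 10, tolerance = 0.01)
  expect_lt(abs(es$a0 - 1), 0.02)
  # the ES picks are the on-line samples (first of each beat by construction)
  expect_equal(es$points$p_mmHg, seq(90, 50, by = -5), tolerance = 1e-9)
})

test_that("a single on-line candidate per beat is a one-step fixed point", {
  loops <- make_linear_loops(slope = 8, a0 = 0.5, n_samples = 1)
  es <- find_es_points(loops, a0_init = 0.5, collapse_threshold = -Inf)
  expect_true(es$converged)
  expect_equal(es$iterations, 1)
  expect_equal(es$history[1], 0.5, tolerance = 1e-9)
})

test_that("the iterative selection agrees with the exhaustive residual search", {
  loops <- make_linear_loops(slope = 10, a0 = 1, p_es = c(88, 78, 69, 61, 52),
                             n_samples = 10)
  es <- find_es_points(loops, collapse_threshold = -Inf)
  oracle <- brute_force_es(loops)
  expect_equal(dplyr::arrange(es$points, beat)$area_cm2,
               dplyr::arrange(oracle, beat)$area_cm2, tolerance = 1e-12)
  expect_equal(dplyr::arrange(es$points, beat)$p_mmHg,
               dplyr::arrange(oracle, beat)$p_mmHg, tolerance = 1e-12)
})

test_that("the A0 update contracts on noiseless loops and collapsed beats are excluded", {
  loops <- make_linear_loops(slope = 12, a0 = 0.8)
  es <- find_es_points(loops, a0_init = -3, collapse_threshold = -Inf)
  steps <- abs(diff(c(-3, es$history)))
  expect_true(all(diff(steps) <= 1e-9))
  # beats at or below the obliteration threshold are reported and excluded
  collapsed <- tibble::tibble(beat = 99, area_cm2 = c(0, 0.1, 0.2),
                              p_mmHg = c(40, 42, 44))
  es2 <- find_es_points(dplyr::bind_rows(loops, collapsed),
                        collapse_threshold = 0.25)
  expect_equal(es2$collapsed_beats, 99)
  expect_false(99 %in% es2$points$beat)
  all_collapsed <- tibble::tibble(beat = rep(1:5, each = 2),
                                  area_cm2 = rep(c(0, 0.2), 5),
                                  p_mmHg = rep(c(40, 45), 5))
  expect_error(find_es_points(all_collapsed), "collapsed")
})

test_that("ESPAR fitting reproduces generating polynomials and least-squares identities", {
  a <- c(1, 2, 3, 4.5, 6)
  quad_pts <- tibble::tibble(area_cm2 = a, p_mmHg = -0.5 * a^2 + 9.2 * a + 48)
  f <- fit_espar(quad_pts)
  expect_equal(unname(f$quadratic[["beta2"]]), -0.5, tolerance = 1e-6)
  expect_equal(unname(f$quadratic[["beta1"]]), 9.2, tolerance = 1e-6)
  expect_equal(unname(f$quadratic[["beta0"]]), 48, tolerance = 1e-6)
  # collinear points: quadratic term vanishes
  lin_pts <- tibble::tibble(area_cm2 = a, p_mmHg = 10 * a + 5)
  fl <- fit_espar(lin_pts)
  expect_lt(abs(fl$quadratic[["beta2"]]), 1e-9)
  expect_equal(fl$slope, 10, tolerance = 1e-9)
  expect_equal(fl$area_intercept, -0.5, tolerance = 1e-9)
  # duplicated points equal a weighted fit of the deduplicated set
  dup <- dplyr::bind_rows(lin_pts, lin_pts[3, ])
  fd <- fit_espar(dup)
  w <- c(1, 1, 2, 1, 1)
  fw <- lm(p_mmHg ~ area_cm2, data = lin_pts, weights = w)
  expect_equal(unname(coef(fd$lm_linear)), unname(coef(fw)), tolerance = 1e-9)
  expect_error(fit_espar(lin_pts[1:2, ]), "3")
})

test_that("ESPAR inversion takes the physical branch and clamps at obliteration", {
  lin <- c(beta2 = 0, beta1 = 10, beta0 = -10)    # P = 10 (A - 1)
  expect_equal(as.numeric(area_at_pressure(lin, 60)), 7)
  clamped <- area_at_pressure(c(beta2 = 0, beta1 = 10, beta0 = 20), 10)
  expect_equal(as.numeric(clamped), 0)
  expect_true(attr(clamped, "clamped"))
  # quadratic inversion agrees with a root-finder oracle
  q <- c(beta2 = -0.5, beta1 = 9.2, beta0 = 48)
  for (p in c(55, 60, 75, 88)) {
    root <- uniroot(function(a) q[[1]] * a^2 + q[[2]] * a + q[[3]] - p,
                    c(0, 9.2), tol = 1e-12)$root
    expect_equal(as.numeric(area_at_pressure(q, p)), root, tolerance = 1e-8)
  }
})

test_that("trapezoidal volume reconstruction is exact for linear area profiles", {
  expect_equal(reconstruct_volume(c(0, 2, 4), c(0, 1, 2)), 4, tolerance = 1e-12)
  # linear profile: trapezoid equals c L^2 / 2 for any station set
  L <- 8; cc <- 1.3
  d1 <- c(0, 2, 4, 6, 8); d2 <- sort(c(0, runif(6, 0, L), L))
  expect_equal(reconstruct_volume(cc * d1, d1), cc * L^2 / 2, tolerance = 1e-12)
  expect_equal(reconstruct_volume(cc * d2, d2), cc * L^2 / 2, tolerance = 1e-12)
  # exact linearity in the areas
  a <- c(0, 1.3, 2.9, 4.1, 5)
  expect_equal(reconstruct_volume(2 * a, d1), 2 * reconstruct_volume(a, d1),
               tolerance = 1e-14)
  expect_error(reconstruct_volume(c(1, 2), c(1, 1)), "increasing")
  expect_error(reconstruct_volume(c(-1, 2), c(0, 1)), "negative")
})

test_that("trapezoid error on a truncated semi-ellipsoid shrinks with stations", {
  R <- 2; L <- 8
  area_at <- function(z) pi * R^2 * (1 - (1 - z / L)^2)  # apex at z = 0
  v_true <- 2 / 3 * pi * R^2 * L
  d5 <- seq(0, L, length.out = 5)
  expect_equal(reconstruct_volume(area_at(d5), d5), v_true, tolerance = 0.07)
  d50 <- seq(0, L, length.out = 50)
  expect_equal(reconstruct_volume(area_at(d50), d50), v_true, tolerance = 0.002)
})

test_that("the ESPVR grid spans 50-90 mmHg in 5 mmHg steps and behaves monotonely", {
  fits <- list(apex = c(0, 30, 10), mid = c(0, 20, 5), base = c(0, 10, 2))
  ev <- build_espvr(fits, lv_length_cm = 8, n_boot = 0)
  expect_equal(ev$grid$p_mmHg, seq(50, 90, by = 5))
  expect_equal(nrow(ev$grid), 9)
  expect_true(all(diff(ev$grid$v_ml) > 0))
  expect_true(all(ev$grid$v_ml >= 0))
  expect_error(build_espvr(fits[1:2], 8), "every imaged level")
})

test_that("conductance calibration reproduces the two-point identities", {
  # one baseline beat shaped to extremes 40 / 20, then a drift
  t <- seq(0, 3, by = 0.01)
  v <- 30 + 10 * cos(2 * pi * t)           # ED 40, ES 20
  p <- 50 + 40 * pmax(sin(2 * pi * t), 0)
  rec <- tibble::tibble(t_s = t, v_ml = v, p_mmHg = p)
  out <- calibrate_conductance(rec, 43.1, 35.3, baseline_window = c(0, 1),
                               volume_cutoff_Hz = NULL)
  expect_equal(attr(out, "alpha"), (43.1 - 35.3) / (40 - 20), tolerance = 1e-12)
  expect_equal(attr(out, "alpha"), 0.39, tolerance = 1e-12)
  # corrected ED/ES equal the cine reference exactly
  base <- out$t_s <= 1
  expect_equal(max(out$v_corrected_ml[base]), 43.1, tolerance = 1e-9)
  expect_equal(min(out$v_corrected_ml[base]), 35.3, tolerance = 1e-9)
  # measured already equal to cine: alpha = 1 and the signal is unchanged
  idm <- calibrate_conductance(
    tibble::tibble(t_s = t, v_ml = 39.2 + 3.9 * cos(2 * pi * t), p_mmHg = p),
    43.1, 35.3, baseline_window = c(0, 1), volume_cutoff_Hz = NULL)
  expect_equal(attr(idm, "alpha"), 1, tolerance = 1e-9)
  expect_equal(idm$v_corrected_ml, idm$v_ml, tolerance = 1e-9)
  # idempotence: recalibrating with its own ED/ES is the identity
  again <- calibrate_conductance(
    tibble::tibble(t_s = t, v_ml = out$v_corrected_ml, p_mmHg = p),
    43.1, 35.3, baseline_window = c(0, 1), volume_cutoff_Hz = NULL)
  expect_equal(again$v_corrected_ml, out$v_corrected_ml, tolerance = 1e-9)
  expect_error(calibrate_conductance(
    tibble::tibble(t_s = t, v_ml = rep(30, length(t)), p_mmHg = p),
    43.1, 35.3, baseline_window = c(0, 1)), "coincide")
  expect_error(calibrate_conductance(rec, 35.3, 43.1), "exceed")
})

test_that("body-surface-area indexing is plain arithmetic", {
  expect_equal(index_to_bsa(5.7, 1, 1.5), 5.7)
  expect_equal(index_to_bsa(10, 4, 1.5), 1.25)
  expect_equal(index_to_bsa(4.62, 2, 1), 2.31)
  expect_error(index_to_bsa(1, -2), "positive")
})

test_that("tidiers expose fits as tibbles", {
  set.seed(1)
  loops <- make_linear_loops(area_noise_sd = 0.01, pressure_noise_sd = 0.1)
  f <- fit_espar(find_es_points(loops, collapse_threshold = -Inf))
  td <- tidy(f)
  expect_true(all(c("model", "term", "estimate") %in% names(td)))
  expect_equal(glance(f)$slope, f$slope)
  ev <- build_espvr(list(apex = c(0, 30, 10), mid = c(0, 20, 5),
                         base = c(0, 10, 2)), 8, n_boot = 20)
  expect_equal(nrow(tidy(ev)), 9)
  expect_equal(glance(ev)$e_es, ev$e_es)
})
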