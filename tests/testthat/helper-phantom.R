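# Shared fixtures: reduced-size phantom configurations and synthetic loop
# builders. Everything is generated in code at test time.

fast_cfg <- function(...) {
  phantom_config(image_size_px = 64, n_baseline_beats = 2, n_vco_beats = 6,
                 pressure_fs_Hz = 1000, ...)
}

# Synthetic pressure-area loops from a known linear end-systolic relationship
# P = slope * (A - a0). Each beat's ES sample sits exactly on the line; the
# other samples move away from end systole with falling pressure and rising
# area, so their elastance is strictly lower. Optional measurement noise.
make_linear_loops <- function(slope = 10, a0 = 1, p_es = seq(90, 50, by = -5),
                              n_samples = 10, area_noise_sd = 0,
                              pressure_noise_sd = 0) {
  # irregular per-beat sample spacings so that no non-end-systolic
  # combination of picks is accidentally collinear across beats (spacings
  # linear in the beat index would make every fixed-index combination
  # collinear whenever the ES pressures decline linearly)
  a_step <- c(0.31, 0.42, 0.28, 0.51, 0.37, 0.45, 0.33, 0.48, 0.29, 0.40)
  p_step <- c(5.2, 6.1, 4.4, 7.3, 5.6, 6.6, 4.9, 7.0, 5.9, 6.3)
  dplyr::bind_rows(lapply(seq_along(p_es), function(b) {
    a_es <- a0 + p_es[b] / slope
    j <- seq_len(n_samples) - 1
    k <- (b - 1) %% 10 + 1
    tibble::tibble(
      beat = b,
      area_cm2 = a_es + a_step[k] * j + rnorm(n_samples, sd = area_noise_sd),
      p_mmHg = p_es[b] - p_step[k] * j + rnorm(n_samples, sd = pressure_noise_sd)
    )
  }))
}

# Exhaustive oracle for end-systole selection: over every combination of one
# sample per beat, minimize the residual sum of squares of the P-on-A line.
brute_force_es <- function(loops) {
  beats <- split(loops, loops$beat)
  nb <- length(beats)
  ns <- vapply(beats, nrow, integer(1))
  stopifnot(prod(ns) <= 2e6)   # enumeration guard
  combos <- as.matrix(expand.grid(lapply(ns, seq_len)))
  A <- sapply(seq_len(nb), function(k) beats[[k]]$area_cm2[combos[, k]])
  P <- sapply(seq_len(nb), function(k) beats[[k]]$p_mmHg[combos[, k]])
  sx <- rowSums(A); sy <- rowSums(P)
  sxx <- rowSums(A^2); syy <- rowSums(P^2); sxy <- rowSums(A * P)
  n <- nb
  ssr <- (syy - sy^2 / n) - (sxy - sx * sy / n)^2 / (sxx - sx^2 / n)
  best <- which.min(ssr)
  idx <- combos[best, ]
  dplyr::bind_rows(lapply(seq_len(nb), function(k) beats[[k]][idx[k], ]))
}

# Rasterize an ellipse mask directly (test oracle for geometry).
raster_ellipse <- function(a_cm, b_cm, theta_deg, spacing_mm = 2.0313,
                           n_px = 128, cx = NULL, cy = NULL, ss = 8L) {
  s <- spacing_mm / 10
  cx <- cx %||% ((n_px / 2 - 0.37) * s)
  cy <- cy %||% (-(n_px / 2 - 0.61) * s)
  cov <- rtpvr:::ellipse_coverage(n_px, n_px, s, cx, cy, a_cm, b_cm,
                                  theta_deg, ss = ss)
  cov >= 0.5
}

`%||%` <- function(a, b) if (is.null(a)) b else a
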