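#' @title End-systolic relationship fitting
#' @description Iterative maximal-elastance end-systole detection, ESPAR
#'   fitting, trapezoidal ESPVR reconstruction, conductance calibration and
#'   body-surface-area indexing.
#' @name fits
NULL

# ---- maximal-elastance iteration -------------------------------------------

# Core fixed-point scheme (Kono-style shooting point iterative regression).
# df: tibble with columns beat, x (size: area or volume), p (pressure).
# Each iteration: (1) per beat pick the sample maximizing p/(x - x0);
# (2) regress p on x through the picks; (3) x0 <- area(volume) intercept.
max_elastance_points <- function(df, x0_init = 0, tol = 1e-4, max_iter = 50,
                                 collapse_threshold = -Inf) {
  stopifnot(all(c("beat", "x", "p") %in% names(df)))
  by_beat <- split(df, df$beat)
  collapsed <- vapply(by_beat, function(b) min(b$x) <= collapse_threshold, logical(1))
  usable <- by_beat[!collapsed]
  if (length(usable) == 0) abort("all beats are collapsed; no usable loops")
  if (length(by_beat) >= 5 && length(usable) < 2) {
    abort("fewer than 2 usable (non-collapsed) beats")
  }

  x0 <- x0_init
  history <- numeric(0)
  converged <- FALSE
  picks <- NULL
  for (it in seq_len(max_iter)) {
    picks <- lapply(usable, function(b) {
      ok <- b$x > x0 + 1e-9
      if (!any(ok)) return(NULL)
      bb <- b[ok, , drop = FALSE]
      bb[which.max(bb$p / (bb$x - x0)), , drop = FALSE]
    })
    pts <- dplyr::bind_rows(picks)
    if (nrow(pts) < 2) abort("maximal-elastance selection left fewer than 2 points")
    fit <- lm(p ~ x, data = pts)
    b <- coef(fit)
    if (!is.finite(b[2]) || b[2] <= 0) {
      warn("non-positive elastance slope during iteration; returning last iterate")
      break
    }
    x0_new <- unname(-b[1] / b[2])
    history <- c(history, x0_new)
    if (abs(x0_new - x0) < tol) {
      x0 <- x0_new
      converged <- TRUE
      break
    }
    x0 <- x0_new
  }
  pts <- dplyr::bind_rows(picks)
  fit <- lm(p ~ x, data = pts)
  list(points = pts, x0 = x0, slope = unname(coef(fit)[2]),
       iterations = length(history), converged = converged,
       history = history, collapsed_beats = as.numeric(names(by_beat))[collapsed],
       fit = fit)
}

#' Detect per-beat end-systole by iterative maximal-elastance regression
#'
#' End systole is the sample of each beat that maximizes the elastance
#' `P / (A - A0)`. Because `A0` (the area intercept of the end-systolic
#' pressure-area line) is itself unknown, the scheme iterates: select the
#' maximal-elastance sample per beat for the current `A0`, regress pressure on
#' area through the selected points, update `A0` to the line's area intercept,
#' and repeat until the update falls below `tol`.
#'
#' Beats whose minimum area falls at or below `collapse_threshold` (cavity
#' obliteration) are excluded from the regression and reported.
#'
#' @param loops tibble of synchronized samples with columns `beat`,
#'   `area_cm2`, `p_mmHg` (as built by [build_pa_loops()]).
#' @param a0_init starting area intercept (cm^2); must lie below the smallest
#'   usable area.
#' @param tol convergence tolerance on `A0` (cm^2).
#' @param max_iter iteration cap; non-convergence is flagged, the last
#'   iterate returned.
#' @param collapse_threshold areas at or below this value mark obliterated
#'   beats (cm^2).
#' @return an `es_points` list: `points` (tibble `beat`, `area_cm2`,
#'   `p_mmHg`, and any other loop columns), `a0`, `slope`, `iterations`,
#'   `converged`, `history`, `collapsed_beats`.
#' @export
find_es_points <- function(loops, a0_init = 0, tol = 1e-4, max_iter = 50,
                           collapse_threshold = 0.25) {
  df <- loops |> dplyr::rename(x = "area_cm2", p = "p_mmHg")
  res <- max_elastance_points(df, x0_init = a0_init, tol = tol,
                              max_iter = max_iter,
                              collapse_threshold = collapse_threshold)
  res$points <- res$points |> dplyr::rename(area_cm2 = "x", p_mmHg = "p")
  res$a0 <- res$x0
  structure(res, class = "es_points")
}

# ---- ESPAR fitting ---------------------------------------------------------

#' Fit the end-systolic pressure-area relationship
#'
#' Least squares with pressure regressed on area. The linear form gives the
#' elastance-like slope `E_a` (mmHg/cm^2), the area intercept `A0` (cm^2) and
#' the pressure intercept (fitted pressure at zero area); the quadratic form
#' gives pooled coefficients `(beta2, beta1, beta0)`.
#'
#' @param es_points an `es_points` object from [find_es_points()], or a tibble
#'   with columns `area_cm2`, `p_mmHg`.
#' @param level optional level label (apex/mid/base).
#' @return an `espar_fit` object.
#' @export
fit_espar <- function(es_points, level = NULL) {
  pts <- if (inherits(es_points, "es_points")) es_points$points else as_tibble(es_points)
  if (nrow(pts) < 3) abort("ESPAR fit needs at least 3 end-systolic points")
  lin <- lm(p_mmHg ~ area_cm2, data = pts)
  if (!is.finite(coef(lin)[2])) abort("rank-deficient ESPAR design")
  quad <- NULL
  if (nrow(pts) >= 4 && length(unique(pts$area_cm2)) >= 3) {
    quad <- lm(p_mmHg ~ area_cm2 + I(area_cm2^2), data = pts)
  }
  slope <- unname(coef(lin)[2])
  p0 <- unname(coef(lin)[1])
  structure(list(
    level = level,
    slope = slope,
    area_intercept = -p0 / slope,
    pressure_intercept = p0,
    quadratic = if (!is.null(quad)) {
      c(beta2 = unname(coef(quad)[3]), beta1 = unname(coef(quad)[2]),
        beta0 = unname(coef(quad)[1]))
    },
    es_points = pts,
    lm_linear = lin, lm_quadratic = quad,
    convergence = if (inherits(es_points, "es_points")) {
      list(iterations = es_points$iterations, converged = es_points$converged,
           collapsed_beats = es_points$collapsed_beats)
    }
  ), class = "espar_fit")
}

#' @export
print.espar_fit <- function(x, ...) {
  cat(sprintf("ESPAR fit%s: slope %.3f mmHg/cm^2, A0 %.3f cm^2, P-intercept %.2f mmHg (%d ES points)\n",
              if (!is.null(x$level)) paste0(" [", x$level, "]") else "",
              x$slope, x$area_intercept, x$pressure_intercept, nrow(x$es_points)))
  if (!is.null(x$quadratic)) {
    cat(sprintf("  quadratic: P = %.4f A^2 + %.4f A + %.4f\n",
                x$quadratic[["beta2"]], x$quadratic[["beta1"]], x$quadratic[["beta0"]]))
  }
  invisible(x)
}

# ---- inverting a fitted P(A) -----------------------------------------------

# Rising-branch area of P = b2 A^2 + b1 A + b0; pressures without a real root
# on the branch, or with a negative solution, clamp to 0 (obliteration).
quad_area_at_pressure <- function(b2, b1, b0, p) {
  if (b2 == 0) {
    a <- (p - b0) / b1
    clamped <- a < 0
  } else {
    disc <- b1^2 - 4 * b2 * (b0 - p)
    clamped <- disc < 0
    disc <- pmax(disc, 0)
    r1 <- (-b1 + sqrt(disc)) / (2 * b2)
    r2 <- (-b1 - sqrt(disc)) / (2 * b2)
    # rising branch: dP/dA = b1 + 2 b2 A > 0
    a <- ifelse(b1 + 2 * b2 * r1 > 0, r1, r2)
    clamped <- clamped | a < 0
  }
  structure(pmax(a, 0), clamped = clamped)
}

#' Area on a fitted ESPAR at a given pressure
#'
#' Inverts the fitted pressure-on-area form on its physical (rising) branch.
#' When the solution is negative, or the quadratic has no real root at the
#' requested pressure, the area clamps to zero (cavity obliteration); the
#' returned vector carries a logical `clamped` attribute.
#'
#' @param fit an `espar_fit`, or a numeric coefficient vector
#'   `c(beta2, beta1, beta0)`.
#' @param p_mmHg pressures (mmHg).
#' @param model `"quadratic"` (default, falling back to linear when no
#'   quadratic fit exists) or `"linear"`.
#' @return areas (cm^2), with attribute `clamped`.
#' @export
area_at_pressure <- function(fit, p_mmHg, model = c("quadratic", "linear")) {
  model <- match.arg(model)
  if (is.numeric(fit)) {
    stopifnot(length(fit) == 3)
    return(quad_area_at_pressure(fit[[1]], fit[[2]], fit[[3]], p_mmHg))
  }
  stopifnot(inherits(fit, "espar_fit"))
  if (model == "quadratic" && !is.null(fit$quadratic)) {
    q <- fit$quadratic
    quad_area_at_pressure(q[["beta2"]], q[["beta1"]], q[["beta0"]], p_mmHg)
  } else {
    quad_area_at_pressure(0, fit$slope, fit$pressure_intercept, p_mmHg)
  }
}

# ---- trapezoidal volume ----------------------------------------------------

#' Trapezoidal short-axis volume reconstruction
#'
#' Composite trapezoid over stations along the long axis:
#' `V = sum over i of (A_i + A_{i+1})/2 * (d_{i+1} - d_i)` (areas in cm^2,
#' distances from the apex in cm, volume in ml), plus an optional constant
#' baseline offset.
#'
#' @param areas cross-sectional areas (cm^2), apex to base order.
#' @param distances_cm strictly increasing station distances from the apical
#'   tip (cm).
#' @param baseline_offset_ml constant additive volume (ml), default 0.
#' @return volume in ml.
#' @export
reconstruct_volume <- function(areas, distances_cm, baseline_offset_ml = 0) {
  if (length(areas) != length(distances_cm)) abort("areas and distances differ in length")
  if (any(diff(distances_cm) <= 0)) abort("station distances must be strictly increasing")
  if (any(areas < 0)) abort("negative station areas")
  trapz(distances_cm, areas) + baseline_offset_ml
}

# Assemble the 5-station scheme (apical tip, imaged levels, valve plane) and
# integrate. The valve-plane area extrapolates the trend of the two basal-most
# imaged levels (floored at 0); its distance moves toward the apex as pressure
# falls: d5 = L * (1 - kappa * (90 - P)/90).
lv_station_volume <- function(level_areas, lv_length_cm, level_fractions,
                              pressure_mmHg, valve_kappa = 0.1,
                              baseline_offset_ml = 0) {
  lv <- names(level_fractions)
  a <- unname(level_areas[lv])
  d <- unname(level_fractions[lv]) * lv_length_cm
  n <- length(d)
  d5 <- lv_length_cm * (1 - valve_kappa * (90 - pressure_mmHg) / 90)
  if (d5 <= d[n]) abort("valve plane moved past the basal imaging level; reduce valve_kappa")
  a5 <- max(a[n] + (a[n] - a[n - 1]) / (d[n] - d[n - 1]) * (d5 - d[n]), 0)
  reconstruct_volume(c(0, a, a5), c(0, d, d5), baseline_offset_ml)
}

# ---- ESPVR -----------------------------------------------------------------

#' Build the end-systolic pressure-volume relationship from per-level ESPARs
#'
#' For each pressure on the grid (default 50-90 mmHg in 5 mmHg steps), the
#' per-level end-systolic areas are read off the fitted ESPARs (clamping at
#' zero where a cavity obliterates), assembled into the 5-station trapezoidal
#' scheme (apical tip, the imaged levels, a pressure-dependent valve plane)
#' and integrated. A line and a quadratic are then fitted to the
#' (volume, pressure) grid; the line's slope is the end-systolic elastance
#' `E_ES` and its volume intercept `V0`.
#'
#' @param espar_fits named list (one per imaged level, apex to base order) of
#'   `espar_fit` objects or coefficient vectors `c(beta2, beta1, beta0)`.
#' @param lv_length_cm apex-to-base length (cm).
#' @param level_fractions named slice positions (fractions of `lv_length_cm`)
#'   matching `names(espar_fits)`.
#' @param grid_mmHg pressure grid (mmHg).
#' @param valve_kappa valve-plane descent coefficient.
#' @param model which ESPAR form to invert (`"quadratic"` or `"linear"`).
#' @param baseline_offset_ml constant additive volume (ml).
#' @param n_boot bootstrap replicates (case resampling of grid points) for the
#'   standard error of the quadratic term; 0 disables.
#' @param boot_seed RNG seed for the bootstrap.
#' @return an `espvr` object: `grid` tibble (`p_mmHg`, `v_ml`, per-level
#'   areas), `e_es` (mmHg/ml), `v0` (ml), `quadratic` coefficients
#'   (`beta2`, `beta1`, `beta0` of `P = f(V)`), `beta2_se_boot`.
#' @export
build_espvr <- function(espar_fits, lv_length_cm,
                        level_fractions = c(apex = 0.25, mid = 0.50, base = 0.75),
                        grid_mmHg = seq(50, 90, by = 5),
                        valve_kappa = 0.1,
                        model = "quadratic",
                        baseline_offset_ml = 0,
                        n_boot = 200, boot_seed = 1L) {
  lv <- names(level_fractions)
  if (!all(lv %in% names(espar_fits))) abort("espar_fits must cover every imaged level")
  areas <- sapply(lv, function(l) {
    as.numeric(area_at_pressure(espar_fits[[l]], grid_mmHg, model = model))
  })
  if (length(grid_mmHg) == 1L) areas <- matrix(areas, nrow = 1)
  v <- vapply(seq_along(grid_mmHg), function(i) {
    lv_station_volume(setNames(areas[i, ], lv), lv_length_cm, level_fractions,
                      pressure_mmHg = grid_mmHg[i], valve_kappa = valve_kappa,
                      baseline_offset_ml = baseline_offset_ml)
  }, numeric(1))
  grid <- tibble(p_mmHg = grid_mmHg, v_ml = v)
  for (l in lv) grid[[paste0("area_", l)]] <- areas[, l]

  lin <- lm(p_mmHg ~ v_ml, data = grid)
  e_es <- unname(coef(lin)[2])
  v0 <- -unname(coef(lin)[1]) / e_es
  quad <- lm(p_mmHg ~ v_ml + I(v_ml^2), data = grid)
  qc <- c(beta2 = unname(coef(quad)[3]), beta1 = unname(coef(quad)[2]),
          beta0 = unname(coef(quad)[1]))

  beta2_se <- NA_real_
  if (n_boot > 0) {
    beta2_se <- with_seed(boot_seed, {
      reps <- vapply(seq_len(n_boot), function(i) {
        idx <- sample(nrow(grid), replace = TRUE)
        g <- grid[idx, ]
        if (length(unique(g$v_ml)) < 3) return(NA_real_)
        unname(coef(lm(p_mmHg ~ v_ml + I(v_ml^2), data = g))[3])
      }, numeric(1))
      sd(reps, na.rm = TRUE)
    })
  }

  structure(list(grid = grid, e_es = e_es, v0 = v0,
                 quadratic = qc, beta2_se_boot = beta2_se,
                 lm_linear = lin, lm_quadratic = quad,
                 lv_length_cm = lv_length_cm, level_fractions = level_fractions,
                 valve_kappa = valve_kappa, model = model),
            class = "espvr")
}

#' @export
print.espvr <- function(x, ...) {
  cat(sprintf("ESPVR on %d-point grid [%g, %g] mmHg: E_ES %.3f mmHg/ml, V0 %.2f ml\n",
              nrow(x$grid), min(x$grid$p_mmHg), max(x$grid$p_mmHg), x$e_es, x$v0))
  cat(sprintf("  quadratic: P = %.5f V^2 + %.4f V + %.3f (boot SE of V^2 term: %.5f)\n",
              x$quadratic[["beta2"]], x$quadratic[["beta1"]], x$quadratic[["beta0"]],
              x$beta2_se_boot))
  invisible(x)
}

# ---- conductance catheter --------------------------------------------------

smooth_volume <- function(v, fs, cutoff_Hz) {
  if (is.null(cutoff_Hz) || cutoff_Hz >= fs / 2) return(v)
  bf <- signal::butter(4, cutoff_Hz / (fs / 2), type = "low")
  filtfilt_padded(bf, v)
}

#' Two-point calibration of a conductance volume signal against cine MRI
#'
#' Applies the gain/parallel-conductance correction
#' `V_corr(t) = alpha * (V_cond(t) - V_cond_ES) + V_cine_ES` with
#' `alpha = (V_cine_ED - V_cine_ES) / (V_cond_ED - V_cond_ES)`, so the
#' corrected baseline ED and ES volumes equal the cine reference exactly.
#'
#' @param record tibble with columns `t_s`, `v_ml` (measured volume signal)
#'   and `p_mmHg`.
#' @param cine_ed_ml,cine_es_ml reference ED and ES volumes from cine MRI.
#' @param baseline_window time window `c(start, end)` (s) containing at least
#'   one full baseline beat; the measured ED/ES are its max/min. Defaults to
#'   the first detected beat.
#' @param volume_cutoff_Hz zero-phase low-pass applied to the volume channel
#'   before the two-point extremes are read (ventricular volume has no
#'   physiological content above a few tens of Hz; raw conductance noise
#'   would otherwise inflate the ED-ES swing and bias the gain). Set `NULL`
#'   to disable.
#' @return the record with a `v_corrected_ml` column; attributes `alpha`,
#'   `cond_ed_ml`, `cond_es_ml`, `cine_ed_ml`, `cine_es_ml`.
#' @export
calibrate_conductance <- function(record, cine_ed_ml, cine_es_ml,
                                  baseline_window = NULL,
                                  volume_cutoff_Hz = 15) {
  if (cine_ed_ml <= cine_es_ml) abort("cine ED volume must exceed cine ES volume")
  fs <- infer_fs(record$t_s, what = "conductance record")
  if (is.null(baseline_window)) {
    pf <- filter_pressure(tibble(t_s = record$t_s, p_mmHg = record$p_mmHg),
                          cutoff_Hz = min(30, fs / 4))
    beats <- segment_beats(pf)
    baseline_window <- c(beats$t_start_s[1], beats$t_end_s[1])
  }
  v <- smooth_volume(record$v_ml, fs, volume_cutoff_Hz)
  in_win <- record$t_s >= baseline_window[1] & record$t_s <= baseline_window[2]
  if (!any(in_win)) abort("baseline window contains no samples")
  cond_ed <- max(v[in_win])
  cond_es <- min(v[in_win])
  if (abs(cond_ed - cond_es) < 1e-12) abort("measured ED and ES volumes coincide; cannot calibrate")
  alpha <- (cine_ed_ml - cine_es_ml) / (cond_ed - cond_es)
  out <- record
  out$v_corrected_ml <- alpha * (record$v_ml - cond_es) + cine_es_ml
  attr(out, "alpha") <- alpha
  attr(out, "cond_ed_ml") <- cond_ed
  attr(out, "cond_es_ml") <- cond_es
  attr(out, "cine_ed_ml") <- cine_ed_ml
  attr(out, "cine_es_ml") <- cine_es_ml
  out
}

#' End-systolic elastance from a calibrated conductance record
#'
#' Segments beats on the pressure channel, detects per-beat end systole as
#' the maximal-elastance point with the same iterative regression used for
#' the imaging pipeline, and fits the linear ESPVR through end-systolic
#' points inside `p_range`.
#'
#' @param record calibrated record (output of [calibrate_conductance()]).
#' @param p_range pressures (mmHg) of end-systolic points admitted to the
#'   final linear fit.
#' @param min_beats minimum number of admitted VCO beats.
#' @param v0_init starting volume intercept for the iteration (ml).
#' @param volume_cutoff_Hz zero-phase low-pass on the corrected volume before
#'   end-systole detection (`NULL` to disable).
#' @return list with `e_es` (mmHg/ml), `v0` (ml), `es_points` tibble, and the
#'   underlying `lm` fit.
#' @export
espvr_from_conductance <- function(record, p_range = c(50, 90), min_beats = 10,
                                   v0_init = 0, volume_cutoff_Hz = 15) {
  if (is.null(record$v_corrected_ml)) abort("record must be calibrated first")
  fs <- infer_fs(record$t_s, what = "conductance record")
  pf <- filter_pressure(tibble(t_s = record$t_s, p_mmHg = record$p_mmHg),
                        cutoff_Hz = min(30, fs / 4))
  beats <- segment_beats(pf)
  df <- record |>
    mutate(beat = beat_index_at(.data$t_s, beats),
           v_smooth = smooth_volume(.data$v_corrected_ml, fs, volume_cutoff_Hz),
           p_smooth = pf$p_mmHg) |>
    dplyr::filter(!is.na(.data$beat)) |>
    dplyr::transmute(beat = .data$beat, x = .data$v_smooth, p = .data$p_smooth)
  res <- max_elastance_points(df, x0_init = v0_init, tol = 1e-4, max_iter = 50)
  pts <- res$points |>
    dplyr::filter(.data$p >= p_range[1], .data$p <= p_range[2]) |>
    dplyr::rename(v_ml = "x", p_mmHg = "p")
  if (nrow(pts) < min_beats) {
    abort(sprintf("only %d end-systolic points inside the pressure range (need %d)",
                  nrow(pts), min_beats))
  }
  fit <- lm(p_mmHg ~ v_ml, data = pts)
  e_es <- unname(coef(fit)[2])
  list(e_es = e_es, v0 = -unname(coef(fit)[1]) / e_es,
       es_points = pts, fit = fit, iteration = res)
}

#' Index a hemodynamic quantity to body surface area
#'
#' @param value quantity to index.
#' @param bsa_m2 body surface area (m^2), positive.
#' @param exponent indexing exponent: 1 for elastance, commonly 1.5 for
#'   volumes.
#' @return `value / bsa_m2^exponent`.
#' @export
index_to_bsa <- function(value, bsa_m2, exponent = 1) {
  if (!is.numeric(bsa_m2) || any(bsa_m2 <= 0)) abort("bsa_m2 must be positive")
  value / bsa_m2^exponent
}
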