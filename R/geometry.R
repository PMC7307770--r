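#' @title Shape descriptors of the segmented cavity
#' @description Cavity area, moment-based ellipse fits, orientation relative
#'   to the right-ventricular insertion, obliteration flags and ED/ES marking.
#'
#' Coordinate convention: masks are `[row, col]` matrices, 0-based pixel
#' indices, row increasing downward. Physical coordinates use
#' `x = col * spacing` and `y = -row * spacing` (y up), so orientation angles
#' are counter-clockwise from the +x axis, wrapped to (-90, 90].
#' @name geometry
NULL

#' Cavity cross-sectional area of a binary mask
#'
#' @param mask logical (or 0/1) matrix.
#' @param pixel_spacing_mm pixel spacing (mm); required.
#' @return area in cm^2 (foreground pixel count times the pixel area).
#' @export
cavity_area <- function(mask, pixel_spacing_mm) {
  if (missing(pixel_spacing_mm) || is.null(pixel_spacing_mm)) {
    abort("pixel_spacing_mm metadata is required")
  }
  sum(mask != 0) * (pixel_spacing_mm / 10)^2
}

#' Moment-based ellipse fit of a cavity mask
#'
#' The equal-area ellipse of the foreground's second central moments: full
#' axes are `4 * sqrt(eigenvalues)` of the pixel-coordinate covariance (with
#' the 1/12-pixel finite-bin correction), the orientation is that of the
#' major eigenvector. Robust on the small, noisy masks that occur near cavity
#' obliteration, where boundary least squares breaks down.
#'
#' @param mask logical matrix with at least 16 foreground pixels.
#' @param pixel_spacing_mm pixel spacing (mm).
#' @return an `ellipse_fit` list: `centroid_cm` (x, y), `centroid_px`
#'   (row, col, 0-based), `major_axis_cm`, `minor_axis_cm`, `axis_ratio`,
#'   `orientation_deg` in (-90, 90], `n_px`, and flags `degenerate`
#'   (1-pixel-wide mask) and `ill_conditioned` (axis ratio < 1.02, where
#'   orientation is numerically meaningless).
#' @export
fit_ellipse <- function(mask, pixel_spacing_mm) {
  idx <- which(mask != 0, arr.ind = TRUE)
  n <- nrow(idx)
  if (n < 16) abort("mask too small for an ellipse fit (needs >= 16 pixels)")
  s <- pixel_spacing_mm / 10
  x <- (idx[, "col"] - 1) * s
  y <- -(idx[, "row"] - 1) * s
  mx <- mean(x); my <- mean(y)
  # population covariance + finite-pixel correction
  cxx <- mean((x - mx)^2) + s^2 / 12
  cyy <- mean((y - my)^2) + s^2 / 12
  cxy <- mean((x - mx) * (y - my))
  C <- matrix(c(cxx, cxy, cxy, cyy), 2)
  e <- eigen(C, symmetric = TRUE)
  major <- 4 * sqrt(e$values[1])
  minor <- 4 * sqrt(e$values[2])
  v <- e$vectors[, 1]
  orientation <- wrap_angle_90(atan2(v[2], v[1]) * 180 / pi)
  # a 1-pixel-wide run has minor = 4 * sqrt(s^2/12) ~ 1.155 s
  degenerate <- minor <= s * 1.16
  ratio <- major / minor
  structure(list(
    centroid_cm = c(x = mx, y = my),
    centroid_px = c(row = -my / s, col = mx / s),
    major_axis_cm = major, minor_axis_cm = minor,
    axis_ratio = ratio,
    orientation_deg = orientation,
    n_px = n,
    degenerate = degenerate,
    ill_conditioned = ratio < 1.02
  ), class = "ellipse_fit")
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat(sprintf("ellipse fit: axes %.2f x %.2f cm (ratio %.3f), orientation %.1f deg, %d px%s\n",
              x$major_axis_cm, x$minor_axis_cm, x$axis_ratio, x$orientation_deg,
              x$n_px,
              if (x$ill_conditioned) " [orientation ill-conditioned]" else ""))
  invisible(x)
}

#' Major-axis orientation relative to the RV insertion landmark
#'
#' Signed angle between the (undirected) major axis and the line from the
#' ellipse centroid to the anterior right-ventricular insertion point,
#' wrapped to (-90, 90]; positive angles rotate from the RV line toward the
#' septal side (counter-clockwise in the y-up frame).
#'
#' @param ellipse an `ellipse_fit`.
#' @param rv_insertion_px landmark `c(row, col)` in 0-based pixel units.
#' @param pixel_spacing_mm pixel spacing (mm).
#' @return angle in degrees, (-90, 90].
#' @export
orientation_relative_to_rv <- function(ellipse, rv_insertion_px, pixel_spacing_mm) {
  s <- pixel_spacing_mm / 10
  rv_xy <- c(x = rv_insertion_px[["col"]] * s, y = -rv_insertion_px[["row"]] * s)
  dv <- rv_xy - ellipse$centroid_cm
  if (sqrt(sum(dv^2)) < 1e-9) abort("RV insertion coincides with the centroid")
  psi <- atan2(dv[["y"]], dv[["x"]]) * 180 / pi
  wrap_angle_90(ellipse$orientation_deg - psi)
}

#' Build a per-frame area series from segmentation masks
#'
#' @param masks list of logical masks (one per frame) or a
#'   `segmentation_result`.
#' @param t_s frame times (s); taken from the result when available.
#' @param pixel_spacing_mm pixel spacing (mm).
#' @return tibble `frame`, `t_s`, `area_cm2`.
#' @export
area_series <- function(masks, t_s = NULL, pixel_spacing_mm = NULL) {
  if (inherits(masks, "segmentation_result")) {
    pixel_spacing_mm <- pixel_spacing_mm %||% masks$pixel_spacing_mm
    t_s <- t_s %||% masks$t_s
    masks <- masks$masks
  }
  if (is.null(pixel_spacing_mm)) abort("pixel_spacing_mm metadata is required")
  a <- vapply(masks, cavity_area, numeric(1), pixel_spacing_mm = pixel_spacing_mm)
  tibble(frame = seq_along(masks),
         t_s = t_s %||% (seq_along(masks) - 1),
         area_cm2 = a)
}

#' Flag cavity obliteration on an area series
#'
#' Obliteration is area at or below the threshold (default 0.25 cm^2,
#' inclusive). Shape descriptors at flagged frames should be excluded from
#' downstream axis/orientation analysis.
#'
#' @param series tibble with `area_cm2`.
#' @param threshold_cm2 obliteration threshold (cm^2).
#' @return the series with a logical `obliterated` column.
#' @export
detect_obliteration <- function(series, threshold_cm2 = 0.25) {
  if (nrow(series) == 0) abort("empty area series")
  series$obliterated <- series$area_cm2 <= threshold_cm2
  series
}

#' Mark end-diastolic and end-systolic frames on an area series
#'
#' Within each beat the ED frame is the area maximum and the (provisional) ES
#' frame the area minimum; ties resolve to the first occurrence. The
#' maximal-elastance criterion in [find_es_points()] later refines ES. Beats
#' covering fewer than 3 frames are skipped with a warning.
#'
#' @param series tibble with `t_s`, `area_cm2`.
#' @param beats beat table from [segment_beats()] (pressure clock).
#' @param offset_s alignment offset (`t_pressure = t_area + offset`).
#' @return the series with `beat`, `is_ed`, `is_es` columns.
#' @export
mark_ed_es <- function(series, beats, offset_s = 0) {
  idx <- beat_index_at(series$t_s + offset_s, beats)
  series$beat <- idx
  series$is_ed <- FALSE
  series$is_es <- FALSE
  skipped <- 0L
  for (b in unique(idx[!is.na(idx)])) {
    rows <- which(!is.na(idx) & idx == b)
    if (length(rows) < 3) { skipped <- skipped + 1L; next }
    series$is_ed[rows[which.max(series$area_cm2[rows])]] <- TRUE
    series$is_es[rows[which.min(series$area_cm2[rows])]] <- TRUE
  }
  if (skipped > 0) warn(sprintf("%d beat(s) with fewer than 3 frames skipped", skipped))
  series
}

#' Per-frame geometry table for a segmented sequence
#'
#' Convenience wrapper producing one row per frame: area, ellipse axes, axis
#' ratio, orientation, orientation relative to the RV insertion, and the
#' obliteration flag. Shape descriptors are `NA` at obliterated or too-small
#' frames.
#'
#' @param seg a `segmentation_result` (or list of masks).
#' @param pixel_spacing_mm pixel spacing (mm).
#' @param t_s frame times (s).
#' @param rv_insertion_px optional RV landmark `c(row, col)`.
#' @param threshold_cm2 obliteration threshold.
#' @return tibble with one row per frame.
#' @export
geometry_table <- function(seg, pixel_spacing_mm = NULL, t_s = NULL,
                           rv_insertion_px = NULL, threshold_cm2 = 0.25) {
  if (inherits(seg, "segmentation_result")) {
    pixel_spacing_mm <- pixel_spacing_mm %||% seg$pixel_spacing_mm
    t_s <- t_s %||% seg$t_s
    masks <- seg$masks
  } else masks <- seg
  ser <- area_series(masks, t_s, pixel_spacing_mm) |>
    detect_obliteration(threshold_cm2)
  fits <- lapply(seq_along(masks), function(i) {
    if (ser$obliterated[i] || sum(masks[[i]]) < 16) return(NULL)
    fit_ellipse(masks[[i]], pixel_spacing_mm)
  })
  ser$major_axis_cm <- vapply(fits, function(f) if (is.null(f)) NA_real_ else f$major_axis_cm, 1)
  ser$minor_axis_cm <- vapply(fits, function(f) if (is.null(f)) NA_real_ else f$minor_axis_cm, 1)
  ser$axis_ratio <- vapply(fits, function(f) if (is.null(f)) NA_real_ else f$axis_ratio, 1)
  ser$orientation_deg <- vapply(fits, function(f) if (is.null(f)) NA_real_ else f$orientation_deg, 1)
  if (!is.null(rv_insertion_px)) {
    ser$orientation_rv_deg <- vapply(fits, function(f) {
      if (is.null(f)) NA_real_ else
        orientation_relative_to_rv(f, rv_insertion_px, pixel_spacing_mm)
    }, 1)
  }
  ser
}
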