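#' @title Readers and writers
#' @description Image stacks (multi-frame TIFF, NIfTI) with JSON sidecar
#'   metadata, pressure/contour/loop CSV, configuration YAML and the study
#'   manifest.
#'
#' Units are fixed at cm^2 (area), mmHg (pressure), ml (volume) and degrees
#' (angles); pixel coordinates are (row, col), 0-based, row increasing
#' downward. Conversions happen only at these I/O boundaries.
#' @name cli_io
NULL

sidecar_path <- function(path) paste0(path, ".json")

#' Write an image sequence to disk
#'
#' Frames go to a multi-frame TIFF (16-bit, intensities clamped to \[0, 1\])
#' or a NIfTI volume depending on the file extension; metadata (pixel spacing,
#' frame period, RV landmark, frame times) goes to a JSON sidecar next to the
#' image file.
#'
#' @param sequence an `rt_sequence` or numeric array `[row, col, frame]`.
#' @param path destination ending in `.tif`, `.tiff`, `.nii` or `.nii.gz`.
#' @param pixel_spacing_mm,frame_period_ms metadata when `sequence` is a bare
#'   array.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(sequence, path, pixel_spacing_mm = NULL,
                              frame_period_ms = NULL) {
  if (inherits(sequence, "rt_sequence")) {
    frames <- sequence$frames
    meta <- sequence[setdiff(names(sequence), "frames")]
  } else {
    frames <- sequence
    meta <- list(pixel_spacing_mm = pixel_spacing_mm,
                 frame_period_ms = frame_period_ms)
  }
  if (is.null(meta$pixel_spacing_mm)) abort("pixel_spacing_mm is required")
  # named numeric vectors serialize as bare arrays; keep the landmark's names
  if (!is.null(meta$rv_insertion_px)) {
    meta$rv_insertion_px <- as.list(meta$rv_insertion_px)
  }
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    imgs <- lapply(seq_len(dim(frames)[3]), function(k) clamp(frames[, , k], 0, 1))
    tiff::writeTIFF(imgs, path, bits.per.sample = 16)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::asNifti(frames)
    RNifti::pixdim(img) <- c(meta$pixel_spacing_mm, meta$pixel_spacing_mm,
                             (meta$frame_period_ms %||% 1))
    RNifti::writeNifti(img, path)
  } else abort("unsupported image format (use .tif/.tiff or .nii/.nii.gz)")
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read an image sequence from disk
#'
#' Metadata is resolved from the JSON sidecar when present, otherwise from
#' the NIfTI header; a sidecar value that conflicts with the header wins with
#' a warning. A missing pixel spacing is an error naming the key.
#'
#' @param path a `.tif/.tiff` or `.nii/.nii.gz` file written by
#'   [write_image_stack()] (or compatible).
#' @return an `rt_sequence`.
#' @export
read_image_stack <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  meta <- list()
  if (file.exists(sidecar_path(path))) {
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  }
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    imgs <- tiff::readTIFF(path, all = TRUE)
    frames <- array(unlist(imgs), dim = c(dim(imgs[[1]]), length(imgs)))
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::readNifti(path)
    frames <- array(as.numeric(img), dim = dim(img))
    hdr_spacing <- RNifti::pixdim(img)[1]
    if (is.null(meta$pixel_spacing_mm)) {
      meta$pixel_spacing_mm <- hdr_spacing
    } else if (abs(meta$pixel_spacing_mm - hdr_spacing) > 1e-6) {
      warn(sprintf("sidecar pixel spacing (%g mm) overrides NIfTI header (%g mm)",
                   meta$pixel_spacing_mm, hdr_spacing))
    }
  } else abort("unsupported image format (use .tif/.tiff or .nii/.nii.gz)")
  if (is.null(meta$pixel_spacing_mm)) {
    abort("missing metadata key 'pixel_spacing_mm' (no sidecar or header value)")
  }
  structure(c(list(frames = frames), meta[setdiff(names(meta), "frames")]),
            class = "rt_sequence")
}

#' Read or write a pressure trace CSV (`t_s`, `p_mmHg`)
#'
#' Reading enforces uniform sampling and reports the maximum timestamp jitter
#' when it is violated.
#'
#' @param path CSV path.
#' @param trace tibble with `t_s`, `p_mmHg`.
#' @return a tibble (read) or `path` invisibly (write).
#' @export
read_pressure_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("t_s", "p_mmHg") %in% names(df))) {
    abort("pressure CSV must have columns t_s, p_mmHg")
  }
  infer_fs(df$t_s, what = sprintf("pressure CSV %s", basename(path)))
  as_tibble(df)
}

#' @rdname read_pressure_csv
#' @export
write_pressure_csv <- function(trace, path) {
  utils::write.csv(trace[, c("t_s", "p_mmHg")], path, row.names = FALSE)
  invisible(path)
}

#' Read or write a contour CSV (`x`, `y`, 0-based pixel coordinates)
#' @param path CSV path.
#' @param contour data frame with `x`, `y`.
#' @return a tibble (read) or `path` invisibly (write).
#' @export
read_contour_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("x", "y") %in% names(df))) abort("contour CSV must have columns x, y")
  as_tibble(df)
}

#' @rdname read_contour_csv
#' @export
write_contour_csv <- function(contour, path) {
  utils::write.csv(as.data.frame(contour)[, c("x", "y")], path, row.names = FALSE)
  invisible(path)
}

#' Write segmentation masks as a multi-frame TIFF (0/255)
#' @param masks list of logical matrices or a `segmentation_result`.
#' @param path destination `.tif`.
#' @return `path`, invisibly.
#' @export
write_masks_tiff <- function(masks, path) {
  if (inherits(masks, "segmentation_result")) masks <- masks$masks
  tiff::writeTIFF(lapply(masks, function(m) (m != 0) * 1), path,
                  bits.per.sample = 8)
  invisible(path)
}

#' @rdname write_masks_tiff
#' @export
read_masks_tiff <- function(path) {
  lapply(tiff::readTIFF(path, all = TRUE), function(m) m > 0.5)
}

#' Read a study manifest (YAML)
#'
#' The manifest names the per-level inputs and study-level constants:
#' ```yaml
#' lv_length_cm: 8
#' bsa_m2: 1.3
#' reference_pressure: {ed: 8, peak: 90}
#' levels:
#'   apex: {image: apex.tif, pressure: apex_p.csv, contour: apex_contour.csv}
#'   mid:  {...}
#'   base: {...}
#' conductance: {record: cond.csv, cine_ed_ml: 43.1, cine_es_ml: 35.3}
#' ```
#' Levels must be labeled `apex`, `mid`, `base`, each exactly once, and every
#' referenced file must exist; violations raise an error naming the field.
#'
#' @param path YAML manifest path.
#' @return validated manifest list.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) abort(sprintf("manifest not found: %s", path))
  m <- yaml::read_yaml(path)
  if (is.null(m$levels)) abort("manifest field 'levels' is missing")
  if (!setequal(names(m$levels), c("apex", "mid", "base")) ||
      anyDuplicated(names(m$levels))) {
    abort("manifest field 'levels' must contain apex, mid and base exactly once")
  }
  base_dir <- dirname(path)
  for (lv in names(m$levels)) {
    for (key in c("image", "pressure", "contour")) {
      f <- m$levels[[lv]][[key]]
      if (is.null(f)) abort(sprintf("manifest field 'levels.%s.%s' is missing", lv, key))
      fp <- if (grepl("^/", f)) f else file.path(base_dir, f)
      if (!file.exists(fp)) {
        abort(sprintf("manifest field 'levels.%s.%s' points to a missing file: %s",
                      lv, key, f))
      }
      m$levels[[lv]][[key]] <- fp
    }
  }
  if (is.null(m$lv_length_cm)) abort("manifest field 'lv_length_cm' is missing")
  m
}

#' Write pipeline artifacts to a directory
#'
#' Writes whatever components the result carries: per-level geometry tables
#' and loops as CSV, fits and the ESPVR as JSON summaries.
#'
#' @param result an `rtpvr_result` from [run_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (lv in names(result$levels)) {
    r <- result$levels[[lv]]
    utils::write.csv(r$geometry, file.path(dir, paste0(lv, "_geometry.csv")),
                     row.names = FALSE)
    utils::write.csv(r$loops, file.path(dir, paste0(lv, "_loops.csv")),
                     row.names = FALSE)
    utils::write.csv(r$espar$es_points, file.path(dir, paste0(lv, "_es_points.csv")),
                     row.names = FALSE)
  }
  summary <- list(
    espar = lapply(result$levels, function(r) {
      list(slope_mmHg_cm2 = r$espar$slope,
           area_intercept_cm2 = r$espar$area_intercept,
           pressure_intercept_mmHg = r$espar$pressure_intercept,
           quadratic = as.list(r$espar$quadratic))
    }),
    espvr = list(e_es_mmHg_ml = result$espvr$e_es, v0_ml = result$espvr$v0,
                 quadratic = as.list(result$espvr$quadratic),
                 grid = result$espvr$grid)
  )
  if (!is.null(result$espvr_indexed)) summary$espvr_indexed <- result$espvr_indexed
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
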