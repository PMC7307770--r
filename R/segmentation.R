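#' @title Level-set cavity segmentation with a shape prior
#' @description Frame-propagated two-phase level-set segmentation of the LV
#'   cavity. The first frame is seeded by a manual contour; each subsequent
#'   frame evolves from the previous frame's converged field, which also
#'   serves as an L2 shape prior. Region statistics are computed in a narrow
#'   band around the zero level so the competition is between blood pool and
#'   adjacent myocardium rather than the whole image.
#' @name segmentation
#' @useDynLib rtpvr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Level-set evolution parameters
#'
#' @param lambda_region weight of the two-phase region term.
#' @param mu_curvature weight of the boundary-length (curvature) term; the
#'   explicit scheme requires `dt * mu_curvature <= 1` with the smeared delta
#'   used here.
#' @param beta_shape weight of the L2 shape prior toward the previous frame's
#'   field (treated semi-implicitly, so any non-negative value is stable).
#' @param dt evolution time step.
#' @param max_iter iteration cap per frame.
#' @param tol stopping criterion: fraction of pixels allowed to change label
#'   between reinitialization checkpoints (0 = require an exactly stationary
#'   mask).
#' @param reinit_every iterations between signed-distance reinitializations
#'   (also the convergence checkpoint cadence).
#' @param band_px half-width (pixels) of the narrow band used for region
#'   statistics and the shape term; keep it below the expected myocardial
#'   wall thickness in pixels, or background leaks into the outside mean.
#' @param delta_eps smearing width of the Heaviside/delta pair (pixels).
#' @param min_contrast minimum |inside - outside| band-mean intensity
#'   difference; below it the frame is declared contrast-free and the mask
#'   empty (the cavity-collapse tie-break).
#' @return a `level_set_params` list.
#' @export
level_set_params <- function(lambda_region = 25,
                             mu_curvature = 0.4,
                             beta_shape = 0.15,
                             dt = 0.5,
                             max_iter = 150,
                             tol = 0,
                             reinit_every = 30,
                             band_px = 4,
                             delta_eps = 1.0,
                             min_contrast = 0.05) {
  p <- as.list(environment())
  if (any(unlist(p[c("lambda_region", "mu_curvature", "beta_shape")]) < 0)) {
    abort("weights must be non-negative")
  }
  if (p$max_iter < 1) abort("max_iter must be >= 1")
  if (p$dt * p$mu_curvature > 1) {
    abort("dt * mu_curvature exceeds the stability bound (<= 1) of the explicit curvature step")
  }
  class(p) <- c("level_set_params", "list")
  p
}

# Signed distance field of a mask: negative inside, |phi| = 0.5 px at
# boundary pixels. Empty/full masks get a large constant field.
signed_distance <- function(mask) {
  if (!any(mask)) return(matrix(1e3, nrow(mask), ncol(mask)))
  if (all(mask)) return(matrix(-1e3, nrow(mask), ncol(mask)))
  m <- mask * 1
  d_fg <- EBImage::distmap(m)
  d_bg <- EBImage::distmap(1 - m)
  unclass((d_bg - 0.5) * (1 - m) - (d_fg - 0.5) * m)
}

#' Initialize a level-set field from a manual contour
#'
#' Rasterizes the closed polygon (pixel coordinates `x` = column, `y` = row,
#' 0-based, sub-pixel allowed) and returns the signed-distance field, negative
#' inside, with the zero level within half a pixel of the polygon.
#'
#' @param contour data frame or matrix with columns `x`, `y` (at least 8
#'   vertices).
#' @param frame_shape `c(nrow, ncol)` of the image.
#' @return signed-distance matrix.
#' @export
initialize_from_contour <- function(contour, frame_shape) {
  contour <- as.data.frame(contour)
  if (!all(c("x", "y") %in% names(contour))) {
    names(contour)[1:2] <- c("x", "y")
  }
  if (nrow(contour) < 8) abort("contour must have at least 8 vertices")
  # shoelace area in px^2
  xs <- contour$x; ys <- contour$y
  area <- abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2
  if (area < 4) abort("degenerate contour (area < 4 px)")
  if (min(xs) < 0 || min(ys) < 0 || max(xs) > frame_shape[2] - 1 ||
      max(ys) > frame_shape[1] - 1) {
    abort("contour extends outside the frame")
  }
  grid <- expand.grid(row0 = 0:(frame_shape[1] - 1), col0 = 0:(frame_shape[2] - 1))
  inside <- pracma::inpolygon(grid$col0, grid$row0, xs, ys, boundary = TRUE)
  mask <- matrix(inside, frame_shape[1], frame_shape[2])
  signed_distance(mask)
}

#' Segment a single frame by shape-prior level-set evolution
#'
#' Minimizes a two-phase piecewise-constant region energy plus a curvature
#' (boundary length) penalty and an L2 shape prior toward `prior_field`,
#' starting from `prior_field` itself. Region means are computed within a
#' narrow band of the current zero level. The field is reinitialized to a
#' signed distance every `reinit_every` iterations; convergence is declared
#' when the binary mask is stationary between checkpoints. If the band shows
#' no intensity contrast the cavity is declared absent (empty mask) — this is
#' both the uniform-image tie-break and the collapse mechanism.
#'
#' @param image numeric matrix (finite values).
#' @param prior_field signed-distance field from the previous frame or from
#'   [initialize_from_contour()].
#' @param params a [level_set_params()].
#' @param reference_means optional `c(inside, outside)` band means of the
#'   seeded first frame. The cavity is the bright phase fixed at seeding;
#'   when the evolving inside mean falls below the midpoint of the reference
#'   means the blood pool has vanished and the mask is declared empty, which
#'   prevents the contour from migrating to the myocardium/background
#'   two-phase split after obliteration.
#' @return list: `mask` (logical), `field`, `converged`, `empty`,
#'   `iterations`, `energy` (per-iteration trace), `c1`, `c2`.
#' @export
segment_frame <- function(image, prior_field, params = level_set_params(),
                          reference_means = NULL) {
  if (!all(is.finite(image))) abort("image contains non-finite values")
  if (!all(dim(image) == dim(prior_field))) abort("image / prior shape mismatch")
  phi <- prior_field
  prev_mask <- phi < 0
  energy <- numeric(0)
  iters <- 0L
  converged <- FALSE
  c1 <- NA_real_; c2 <- NA_real_
  while (iters < params$max_iter) {
    chunk <- min(params$reinit_every, params$max_iter - iters)
    res <- cv_evolve(phi, image, prior_field,
                     params$lambda_region, params$mu_curvature,
                     params$beta_shape, params$dt, params$band_px,
                     params$delta_eps, chunk)
    phi <- res$phi
    energy <- c(energy, res$energy)
    c1 <- res$c1; c2 <- res$c2
    iters <- iters + chunk
    mask <- phi < 0
    changed <- sum(mask != prev_mask)
    if (changed <= params$tol * length(mask)) {
      converged <- TRUE
      phi <- signed_distance(mask)
      break
    }
    prev_mask <- mask
    phi <- signed_distance(mask)
  }
  # emptiness rules, evaluated on the settled state only: no two-phase
  # structure left in the band, or the inside mean has left the blood-pool
  # intensity class (cavity obliterated)
  lost_pool <- !is.null(reference_means) && c1 < mean(reference_means)
  if (abs(c1 - c2) < params$min_contrast || lost_pool) {
    return(list(mask = matrix(FALSE, nrow(image), ncol(image)),
                field = matrix(1e3, nrow(image), ncol(image)),
                converged = TRUE, empty = TRUE, iterations = iters,
                energy = energy, c1 = c1, c2 = c2))
  }
  mask <- phi < 0
  mask <- postprocess_mask(mask, prior_field < 0)
  if (!any(mask)) {
    return(list(mask = mask, field = matrix(1e3, nrow(image), ncol(image)),
                converged = converged, empty = TRUE, iterations = iters,
                energy = energy, c1 = c1, c2 = c2))
  }
  list(mask = mask, field = signed_distance(mask), converged = converged,
       empty = FALSE, iterations = iters, energy = energy, c1 = c1, c2 = c2)
}

# Keep the single connected component with maximal overlap with the prior
# (largest component if none overlaps) and fill holes.
postprocess_mask <- function(mask, prior_mask) {
  if (!any(mask)) return(mask)
  lab <- EBImage::bwlabel(mask * 1)
  n <- max(lab)
  if (n > 1) {
    overlap <- tabulate(lab[prior_mask & lab > 0], nbins = n)
    pick <- if (any(overlap > 0)) which.max(overlap) else which.max(tabulate(lab[lab > 0], nbins = n))
    mask <- lab == pick
  }
  as.matrix(EBImage::fillHull(mask * 1)) > 0
}

#' Segment a whole image sequence from one initial contour
#'
#' The first frame is seeded by the manual contour; afterwards the prior for
#' frame `t + 1` is the converged field of frame `t`. After an empty
#' (collapsed) mask the last non-empty field remains the prior so the cavity
#' can be re-acquired when it reopens.
#'
#' @param sequence an `rt_sequence` (from the phantom or [read_image_stack()])
#'   or a numeric array `[row, col, frame]`.
#' @param initial_contour data frame with `x`, `y` polygon vertices, or a
#'   logical mask of the first-frame cavity.
#' @param params a [level_set_params()].
#' @return a `segmentation_result`: `masks` (list of logical matrices),
#'   `status` tibble (`frame`, `converged`, `empty`, `iterations`),
#'   `pixel_spacing_mm`, `t_s`.
#' @export
segment_sequence <- function(sequence, initial_contour,
                             params = level_set_params()) {
  if (inherits(sequence, "rt_sequence")) {
    frames <- sequence$frames
    spacing <- sequence$pixel_spacing_mm
    t_s <- sequence$t_s
  } else {
    frames <- sequence
    spacing <- NULL
    t_s <- NULL
  }
  nf <- dim(frames)[3]
  shape <- dim(frames)[1:2]
  if (is.matrix(initial_contour) && is.logical(initial_contour)) {
    prior <- signed_distance(initial_contour)
  } else {
    prior <- initialize_from_contour(initial_contour, shape)
  }
  masks <- vector("list", nf)
  status <- vector("list", nf)
  ref_means <- NULL
  for (k in seq_len(nf)) {
    res <- segment_frame(frames[, , k], prior, params,
                         reference_means = ref_means)
    masks[[k]] <- res$mask
    status[[k]] <- tibble(frame = k, converged = res$converged,
                          empty = res$empty, iterations = res$iterations)
    if (!res$empty) prior <- res$field
    if (k == 1L && !res$empty) ref_means <- c(res$c1, res$c2)
  }
  structure(list(masks = masks, status = dplyr::bind_rows(status),
                 params = params, pixel_spacing_mm = spacing, t_s = t_s),
            class = "segmentation_result")
}

#' Dice similarity coefficient of two masks
#'
#' `2 |A intersect B| / (|A| + |B|)`; 1 when both masks are empty, 0 when
#' exactly one is.
#'
#' @param mask_a,mask_b logical matrices of identical shape.
#' @return Dice fraction in \[0, 1\].
#' @export
dice <- function(mask_a, mask_b) {
  if (!all(dim(mask_a) == dim(mask_b))) abort("mask shape mismatch")
  dice_cpp(matrix(as.integer(mask_a != 0), nrow(mask_a)),
           matrix(as.integer(mask_b != 0), nrow(mask_b)))
}
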