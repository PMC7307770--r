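#' @importFrom rlang %||% abort warn
#' @importFrom tibble tibble as_tibble
#' @importFrom stats lm coef sd median quantile approx rnorm setNames predict uniroot
#' @import dplyr
NULL

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's .Random.seed afterwards.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

clamp <- function(x, lo = -Inf, hi = Inf) pmin(pmax(x, lo), hi)

# Wrap an undirected-axis angle (degrees) into (-90, 90].
wrap_angle_90 <- function(theta) {
  out <- ((theta + 90) %% 180) - 90
  out[out <= -90] <- out[out <= -90] + 180
  # map exactly -90 to +90 (undirected axis)
  out[abs(out + 90) < 1e-12] <- 90
  out
}

# Composite trapezoid of area (cm^2) over distance (cm) -> ml.
trapz <- function(x, y) sum(0.5 * (y[-1] + y[-length(y)]) * diff(x))

# Uniform sampling rate of a time vector, with jitter check.
infer_fs <- function(t_s, tol = 1e-6, what = "time vector") {
  dt <- diff(t_s)
  if (length(dt) < 1L) abort(paste0(what, " has fewer than 2 samples"))
  jitter <- max(abs(dt - median(dt)))
  if (jitter > tol * max(median(dt), 1e-12)) {
    abort(sprintf("%s is not uniformly sampled (max jitter %.3g s)", what, jitter))
  }
  1 / median(dt)
}

# Zero-phase filtering with odd-symmetric end padding (filtfilt alone has
# large edge transients on signals with non-zero ends).
filtfilt_padded <- function(filt, x, pad = NULL) {
  n <- length(x)
  L <- min(n - 1L, pad %||% max(50L, 3L * max(length(filt$b), length(filt$a)) * 10L))
  head_pad <- 2 * x[1] - x[(L + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - L)]
  y <- signal::filtfilt(filt, c(head_pad, x, tail_pad))
  as.numeric(y[(L + 1):(L + n)])
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a positive finite scalar", name))
  }
}
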