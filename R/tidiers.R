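#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an ESPAR fit
#'
#' One row per coefficient of the linear and (when present) quadratic
#' pressure-on-area forms.
#'
#' @param x an `espar_fit`.
#' @param ... unused.
#' @return a tibble with `model`, `term`, `estimate`, `std.error`.
#' @export
tidy.espar_fit <- function(x, ...) {
  s <- summary(x$lm_linear)$coefficients
  out <- tibble(model = "linear",
                term = c("pressure_intercept", "slope"),
                estimate = s[, 1], std.error = s[, 2])
  if (!is.null(x$lm_quadratic)) {
    q <- summary(x$lm_quadratic)$coefficients
    out <- dplyr::bind_rows(out, tibble(
      model = "quadratic", term = c("beta0", "beta1", "beta2"),
      estimate = q[, 1], std.error = q[, 2]))
  }
  out
}

#' @rdname tidy.espar_fit
#' @export
glance.espar_fit <- function(x, ...) {
  tibble(slope = x$slope, area_intercept = x$area_intercept,
         pressure_intercept = x$pressure_intercept,
         n_points = nrow(x$es_points),
         r.squared = summary(x$lm_linear)$r.squared,
         converged = x$convergence$converged %||% NA,
         iterations = x$convergence$iterations %||% NA_integer_)
}

#' Tidy an ESPVR
#'
#' @param x an `espvr`.
#' @param ... unused.
#' @return `tidy()`: the pressure grid with reconstructed volumes;
#'   `glance()`: one row with `e_es`, `v0` and the quadratic term.
#' @export
tidy.espvr <- function(x, ...) x$grid

#' @rdname tidy.espvr
#' @export
glance.espvr <- function(x, ...) {
  tibble(e_es = x$e_es, v0 = x$v0,
         beta2 = x$quadratic[["beta2"]],
         beta1 = x$quadratic[["beta1"]],
         beta0 = x$quadratic[["beta0"]],
         beta2_se_boot = x$beta2_se_boot,
         n_grid = nrow(x$grid))
}
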