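#' @title Plotting
#' @description ggplot2 views of the pipeline's tabular products.
#' @name plots
#' @import ggplot2
NULL

#' Plot a cavity-area time series
#'
#' Marks ED (green) and ES (red) frames when present and shades obliterated
#' frames.
#'
#' @param series area series tibble (optionally after [mark_ed_es()] /
#'   [detect_obliteration()]).
#' @return a ggplot.
#' @export
plot_area_series <- function(series) {
  p <- ggplot(series, aes(x = .data$t_s, y = .data$area_cm2)) +
    geom_line(color = "grey40") +
    labs(x = "time (s)", y = expression("LV area (cm"^2 * ")"))
  if (!is.null(series$obliterated) && any(series$obliterated)) {
    p <- p + geom_point(data = series[series$obliterated, ],
                        color = "orange", shape = 4)
  }
  if (!is.null(series$is_ed)) {
    p <- p +
      geom_point(data = series[series$is_ed, ], color = "darkgreen", size = 2) +
      geom_point(data = series[series$is_es, ], color = "red", size = 2)
  }
  p
}

#' Plot pressure-area loops with an optional ESPAR overlay
#'
#' @param loops loop tibble from [build_pa_loops()].
#' @param espar optional `espar_fit` whose linear (blue) and quadratic
#'   (green) forms are overlaid with the ES points.
#' @return a ggplot.
#' @export
plot_pa_loops <- function(loops, espar = NULL) {
  p <- ggplot(loops, aes(x = .data$area_cm2, y = .data$p_mmHg,
                         group = .data$beat)) +
    geom_path(alpha = 0.4, color = "grey30") +
    labs(x = expression("LV area (cm"^2 * ")"), y = "LV pressure (mmHg)")
  if (!is.null(espar)) {
    rng <- range(loops$area_cm2)
    a <- seq(rng[1], rng[2], length.out = 100)
    lin <- tibble(a = a, p = espar$pressure_intercept + espar$slope * a)
    p <- p + geom_line(data = lin, aes(x = .data$a, y = .data$p),
                       inherit.aes = FALSE, color = "blue")
    if (!is.null(espar$quadratic)) {
      q <- espar$quadratic
      qd <- tibble(a = a, p = q[["beta2"]] * a^2 + q[["beta1"]] * a + q[["beta0"]])
      p <- p + geom_line(data = qd, aes(x = .data$a, y = .data$p),
                         inherit.aes = FALSE, color = "darkgreen")
    }
    p <- p + geom_point(data = espar$es_points,
                        aes(x = .data$area_cm2, y = .data$p_mmHg),
                        inherit.aes = FALSE, color = "red", size = 2)
  }
  p
}

#' @export
autoplot.espvr <- function(object, ...) {
  g <- object$grid
  rng <- range(g$v_ml)
  v <- seq(rng[1], rng[2], length.out = 100)
  q <- object$quadratic
  ggplot(g, aes(x = .data$v_ml, y = .data$p_mmHg)) +
    geom_point(size = 2) +
    geom_abline(slope = object$e_es, intercept = -object$e_es * object$v0,
                color = "blue") +
    geom_line(data = tibble(v = v, p = q[["beta2"]] * v^2 + q[["beta1"]] * v + q[["beta0"]]),
              aes(x = .data$v, y = .data$p), color = "red", linetype = "dashed") +
    labs(x = "ES volume (ml)", y = "ES pressure (mmHg)",
         title = sprintf("ESPVR: E_ES %.2f mmHg/ml, V0 %.1f ml",
                         object$e_es, object$v0))
}

#' @export
autoplot.espar_fit <- function(object, ...) {
  plot_pa_loops(object$es_points |> mutate(beat = .data$beat), espar = object)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
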