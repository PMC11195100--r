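#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_tile
#'   labs theme_minimal scale_fill_manual facet_wrap
#' @export
ggplot2::autoplot

#' Plot a simulated trace
#'
#' Membrane potential (current clamp) or clamp current (voltage clamp)
#' against time; one facet per sweep for step families.
#'
#' @param object A `sim_trace`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.sim_trace <- function(object, ...) {
  vc <- all(object$mode == "vc")
  df <- as_tibble(object)
  df$y <- if (vc) df$i_clamp else df$vm
  p <- ggplot(df, aes(x = .data$time_ms / 1000, y = .data$y)) +
    geom_line(linewidth = 0.3) +
    labs(x = "time (s)",
         y = if (vc) "clamp current (pA)" else "membrane potential (mV)") +
    theme_minimal()
  if (length(unique(df$sweep)) > 1) {
    p <- p + facet_wrap(~sweep, scales = "free_x")
  }
  p
}

#' Plot an I-V curve
#'
#' @param object An `iv_curve`.
#' @param density Plot current density rather than raw current.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.iv_curve <- function(object, density = TRUE, ...) {
  y <- if (density) object$density_pa_pf else object$current_pa
  ggplot(tibble(v = object$step_mv, y = y), aes(.data$v, .data$y)) +
    geom_line() + geom_point() +
    labs(x = "step potential (mV)",
         y = if (density) "current density (pA/pF)" else "current (pA)") +
    theme_minimal()
}

#' Plot a Boltzmann fit with its data
#'
#' @param object A `boltzmann_fit`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.boltzmann_fit <- function(object, ...) {
  vv <- seq(min(object$data$v), max(object$data$v), length.out = 200)
  sgn <- if (object$kind == "activation") 1 else -1
  yy <- object$ymax / (1 + exp(sgn * (object$v_half - vv) / object$k))
  ggplot(object$data, aes(.data$v, .data$y)) +
    geom_point() +
    geom_line(data = tibble(v = vv, y = yy), aes(.data$v, .data$y)) +
    labs(x = "potential (mV)", y = "I / Imax") +
    theme_minimal()
}

#' Plot a two-conductance regime map
#'
#' Tile map of the firing classification over the conductance grid.
#'
#' @param object A `regime_map`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.regime_map <- function(object, ...) {
  axes <- attr(object, "axes")
  ggplot(as_tibble(object),
         aes(.data$g1, .data$g2, fill = .data$activity)) +
    geom_tile(color = "white") +
    labs(x = paste0("g_", axes$axis1$channel, " (nS)"),
         y = paste0("g_", axes$axis2$channel, " (nS)"),
         fill = "activity") +
    theme_minimal()
}
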