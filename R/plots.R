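# ggplot2 views of the result objects.

#' Plot a response surface
#'
#' Filled surface of the predicted response over the standardized
#' trait-environment plane, one panel per variety, with the stationary point
#' (when inside the plotted window) and the observed environmental range
#' marked.
#'
#' @param object A `te_surface`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.te_surface <- function(object, ...) {
  grid <- object$grid
  p <- ggplot2::ggplot(grid, ggplot2::aes(.data$trait_z, .data$env_z)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$predicted)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$predicted),
                          colour = "white", alpha = 0.6, linewidth = 0.3) +
    ggplot2::scale_fill_viridis_c(name = object$response) +
    ggplot2::geom_hline(yintercept = object$env_range, linetype = "dotted") +
    ggplot2::labs(
      x = paste0(object$trait, " (standardized)"),
      y = paste0(object$env, " (standardized)"),
      caption = "dotted lines: observed environmental range"
    ) +
    ggplot2::theme_minimal()
  if (!all(is.na(grid$variety))) {
    p <- p + ggplot2::facet_wrap(~variety)
  }
  st <- dplyr::filter(object$stationary, !is.na(.data$T_star),
                      abs(.data$T_star) <= max(abs(grid$trait_z)),
                      abs(.data$E_star) <= max(abs(grid$env_z)))
  if (nrow(st)) {
    p <- p + ggplot2::geom_point(
      data = st, ggplot2::aes(.data$T_star, .data$E_star), shape = 4,
      colour = "red", size = 2
    )
  }
  p
}

#' Plot trait-environment relationships
#'
#' One line per variety: the trait-performance slope phi as a function of
#' the standardized environment, faceted by trait-environment pair. Pairs
#' whose interaction was not retained plot as horizontal lines at the trait
#' main effect.
#'
#' @param object A `te_slope_table` (or single [phi_slope()] row).
#' @param env_limits Standardized environment range to draw. Default c(-2, 2).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.te_phi <- function(object, env_limits = c(-2, 2), ...) {
  E <- seq(env_limits[1], env_limits[2], length.out = 50L)
  lines <- dplyr::reframe(
    dplyr::group_by(object, .data$trait, .data$env, .data$variety,
                    .data$retained),
    E = E, phi = .data$intercept[1] + .data$slope[1] * E
  )
  ggplot2::ggplot(lines, ggplot2::aes(.data$E, .data$phi,
                                      colour = .data$variety)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::facet_grid(ggplot2::vars(.data$trait), ggplot2::vars(.data$env)) +
    ggplot2::labs(x = "environment (standardized)",
                  y = "trait-performance slope phi") +
    ggplot2::theme_minimal()
}

#' Plot residual diagnostics
#'
#' Residual-versus-fitted and normal quantile-quantile panels.
#'
#' @param object A `te_diagnostics`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.te_diagnostics <- function(object, ...) {
  d <- object$data
  long <- dplyr::bind_rows(
    tibble::tibble(panel = "residuals vs fitted", x = d$fitted, y = d$residual),
    tibble::tibble(panel = "normal Q-Q", x = d$theoretical_quantile,
                   y = d$residual)
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = NULL, y = "conditional residual") +
    ggplot2::theme_minimal()
}
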