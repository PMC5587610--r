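#' Plot an oxygen tension map
#'
#' @param object A [po2_map()].
#' @param ... Unused.
#' @return A ggplot raster of the tension field (invalid pixels blank), with
#'   depth on the x axis and the vertical scan position on y.
#' @method autoplot po2_map
#' @export
autoplot.po2_map <- function(object, ...) {
  df <- tibble::tibble(
    y_um = rep((seq_len(nrow(object$po2_mmHg)) - 0.5) * object$y_pixel_um,
               times = ncol(object$po2_mmHg)),
    z_um = rep((seq_len(ncol(object$po2_mmHg)) - 0.5) * object$z_pixel_um,
               each = nrow(object$po2_mmHg)),
    po2 = as.vector(object$po2_mmHg))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z_um, y = .data$y_um,
                                   fill = .data$po2)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90",
                                  name = expression(PO[2] ~ "(mmHg)")) +
    ggplot2::labs(x = "axial position (um)", y = "vertical position (um)",
                  title = paste(object$channel, "oxygen tension")) +
    ggplot2::coord_fixed()
}

#' Plot tissue tension depth profiles
#'
#' @param profiles An [extract_profiles()] tibble.
#' @param alpha Line transparency.
#' @return A ggplot of tPO2 against fractional retinal depth, one line per
#'   profile, with the inner/outer boundary marked at 50% depth.
#' @export
plot_depth_profiles <- function(profiles, alpha = 0.4) {
  ggplot2::ggplot(
    profiles[profiles$usable, ],
    ggplot2::aes(x = .data$fractional_depth, y = .data$tpo2_mmHg,
                 group = .data$profile)) +
    ggplot2::geom_line(alpha = alpha) +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = "fractional retinal depth (0 = inner surface)",
                  y = expression(tPO[2] ~ "(mmHg)"))
}

#' Plot a three-layer diffusion fit
#'
#' @param object A [fit_three_layer()] result.
#' @param ... Unused.
#' @return A ggplot of observed outer-retinal tension samples and the fitted
#'   linear-quadratic-linear profile against fractional retinal depth.
#' @method autoplot three_layer_fit
#' @export
autoplot.three_layer_fit <- function(object, ...) {
  grid <- tibble::tibble(x_frac = seq(0, 1, length.out = 201))
  grid$po2 <- three_layer_po2(grid$x_frac, object$params)
  grid$fractional_depth <- 1 - grid$x_frac / 2
  ggplot2::ggplot() +
    ggplot2::geom_point(data = object$fitted,
                        ggplot2::aes(x = .data$fractional_depth,
                                     y = .data$observed)) +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(x = .data$fractional_depth,
                                    y = .data$po2),
                       color = "steelblue") +
    ggplot2::labs(
      x = "fractional retinal depth", y = expression(tPO[2] ~ "(mmHg)"),
      title = sprintf("three-layer fit: QO2 = %.3f mL O2/100g/min",
                      object$qo2_mlo2_per_100g_min))
}
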