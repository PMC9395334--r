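# ggplot2 autoplot methods for the package's result types.

#' @method autoplot mpp
#' @export
autoplot.mpp <- function(object, ...) {
  w <- pattern_window(object)
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::coord_fixed(xlim = w[1:2], ylim = rev(w[3:4]), expand = FALSE) +
    ggplot2::labs(x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
  if ("mark" %in% names(df)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = factor(.data$mark)), ...) +
      ggplot2::labs(colour = "mark")
  } else {
    p + ggplot2::geom_point(...)
  }
}

#' @export
plot.mpp <- function(x, ...) print(autoplot(x, ...))

#' @method autoplot sppa_fn
#' @export
autoplot.sppa_fn <- function(object, ...) {
  stat <- attr(object, "statistic") %||% "summary function"
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$r)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$theoretical), linetype = "dashed",
                       colour = "grey50", na.rm = TRUE) +
    ggplot2::geom_line(ggplot2::aes(y = .data$estimate), na.rm = TRUE, ...) +
    ggplot2::labs(x = "r (px)", y = stat,
                  title = sprintf("%s estimate (dashed: reference model)", stat)) +
    ggplot2::theme_minimal()
}

#' @export
plot.sppa_fn <- function(x, ...) print(autoplot(x, ...))

#' @method autoplot sppa_fn_matrix
#' @export
autoplot.sppa_fn_matrix <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$r)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$theoretical), linetype = "dashed",
                       colour = "grey50", na.rm = TRUE) +
    ggplot2::geom_line(ggplot2::aes(y = .data$estimate), na.rm = TRUE, ...) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$l), cols = ggplot2::vars(.data$m)) +
    ggplot2::labs(x = "r (px)", y = "p_lm(r)",
                  title = "Mark connection functions (dashed: independence p_l p_m)") +
    ggplot2::theme_minimal()
}

#' @method autoplot sppa_envelope
#' @export
autoplot.sppa_envelope <- function(object, ...) {
  stat <- attr(object, "statistic") %||% "statistic"
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$r)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "grey80", na.rm = TRUE) +
    ggplot2::geom_line(ggplot2::aes(y = .data$theoretical), linetype = "dashed",
                       colour = "grey40", na.rm = TRUE) +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed), na.rm = TRUE, ...) +
    ggplot2::labs(x = "r (px)", y = stat,
                  title = sprintf("%s with %s envelope (%d sims, rank %d)", stat,
                                  attr(object, "null"), attr(object, "n_sim"),
                                  attr(object, "rank"))) +
    ggplot2::theme_minimal()
}

#' @export
plot.sppa_envelope <- function(x, ...) print(autoplot(x, ...))

#' @method autoplot raster_scene
#' @export
autoplot.raster_scene <- function(object, channel = 1L, ...) {
  px <- object$pixels[, , channel]
  df <- tibble(
    y = rep(seq_len(nrow(px)) - 0.5, times = ncol(px)),
    x = rep(seq_len(ncol(px)) - 0.5, each = nrow(px)),
    intensity = as.vector(px)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(title = sprintf("%s (channel %d)", object$scene_id, channel)) +
    ggplot2::theme_minimal()
}
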