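# ggplot2 views of the result types.

#' Plot a kymograph
#'
#' Position (along the filament) versus time, coloured by fluorescence
#' level; the region beyond the barbed end is blanked.
#'
#' @param object,x A [render_kymograph()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_kymograph <- function(x, ...) {
  df <- tidyr::expand_grid(
    frame = seq_len(nrow(x$intensity)),
    site = seq_len(ncol(x$intensity))
  )
  df$time <- x$frame_times[df$frame]
  df$position_um <- df$site * x$site_length_nm / 1000
  df$level <- as.vector(t(x$intensity))[
    (df$frame - 1) * ncol(x$intensity) + df$site]
  df <- df[df$level >= 0, ]
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$position_um,
                                   fill = factor(.data$level))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(
      values = c(`0` = "black", `1` = "#b266b2", `2` = "#ff66ff"),
      name = "fluorescence") +
    ggplot2::labs(x = "time (s)", y = "position (µm)") +
    ggplot2::theme_minimal()
}

#' @rdname plot_kymograph
#' @export
autoplot.kymograph <- function(object, ...) plot_kymograph(object, ...)

#' @export
autoplot.hill_fit <- function(object, ...) {
  grid <- tibble::tibble(
    L = exp(seq(log(min(object$data$L)), log(max(object$data$L)),
                length.out = 200)))
  grid$th <- object$A / (1 + (object$ec50 / grid$L)^object$n)
  ggplot2::ggplot(object$data, ggplot2::aes(.data$L, .data$th)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "#7a0177") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "concentration", y = "occupancy",
                  subtitle = sprintf("Hill n = %.3g, EC50 = %.3g",
                                     object$n, object$ec50)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.km_curve <- function(object, ...) {
  df <- tibble::tibble(time = c(0, object$time),
                       survival = c(1, object$survival))
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "residence time (s)", y = "fraction still bound") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.lattice_hill <- function(object, ...) {
  p <- autoplot(object$fit)
  p + ggplot2::labs(
    x = expression(k[on] ~ (s^-1)), y = "coverage",
    title = sprintf("k_off = %g, w = %g, c = %g",
                    object$params$k_off, object$params$w, object$params$c))
}

#' @export
autoplot.bootstrap_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$occupancy_bin,
                                       .data$mean_fraction)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(.data$mean_fraction - .data$sd_fraction, 0),
                   ymax = pmin(.data$mean_fraction + .data$sd_fraction, 1)),
      width = 0.2) +
    ggplot2::labs(x = "occupancy at second binding",
                  y = "fraction overlapping",
                  subtitle = sprintf("c = %g, %d bootstrap replicates",
                                     object$c[1], object$n_boot[1])) +
    ggplot2::theme_minimal()
}
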