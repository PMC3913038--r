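# ggplot2 autoplot() methods for the package's result types.

#' @export
autoplot.ld_field <- function(object, ...) {
  if (is.null(object$image)) abort("field was generated with render = FALSE; nothing to plot.")
  px <- attr(object, "pixel_size")
  df <- purrr::map_dfr(dimnames(object$image)[[3]], function(ch) {
    m <- object$image[, , ch]
    tibble(
      x = rep((seq_len(nrow(m)) - 0.5) * px, times = ncol(m)),
      y = rep((seq_len(ncol(m)) - 0.5) * px, each = nrow(m)),
      intensity = as.vector(m), channel = ch
    )
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~channel) +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", fill = "a.u.")
}

#' @export
autoplot.coloc_result <- function(object, ...) {
  null <- binomial_null(object$n_a, object$s)
  ggplot2::ggplot(null$pmf, ggplot2::aes(x = .data$n, y = .data$prob)) +
    ggplot2::geom_col(width = 0.9, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$n_s, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$n_exp, colour = "red") +
    ggplot2::labs(
      x = "colocalized foci n", y = "P(n) under the random null",
      title = sprintf("n_exp = %d (red) vs null mode n_s = %d: %s",
                      object$n_exp, object$n_s, object$verdict)
    )
}

#' @export
autoplot.bridge_fit <- function(object, ...) {
  grid <- tibble(t = seq(min(object$data$t), max(object$data$t), length.out = 200))
  grid$intensity <- targeting_curve(grid$t, object$tau, object$lag, object$plateau)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$t, y = .data$intensity)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_line(data = grid, colour = "red") +
    ggplot2::labs(x = "time after fusion (min)", y = "LD-associated signal (a.u.)",
                  title = sprintf("tau = %.2f min, lag = %.1f min", object$tau, object$lag))
}

#' @export
autoplot.frap_fit <- function(object, ...) {
  grid <- tibble(t = seq(min(object$data$t), max(object$data$t), length.out = 200))
  grid$intensity <- frap_recovery(grid$t, object$D, object$w, object$beta,
                                  object$immobile)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$t, y = .data$intensity)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_line(data = grid, colour = "red") +
    ggplot2::labs(x = "time after bleach (s)", y = "normalized intensity",
                  title = sprintf("D = %.3g µm²/s", object$D))
}

#' @export
autoplot.ld_density <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$diameter, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "LD diameter (µm)", y = "density")
}

#' @export
autoplot.tension_result <- function(object, ...) {
  ggplot2::ggplot(object$drops,
                  ggplot2::aes(x = seq_len(nrow(object$drops)), y = .data$gamma_mN_m)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$gamma, colour = "red") +
    ggplot2::labs(x = "drop", y = "γ (mN/m)",
                  title = sprintf("γ = %.3g ± %.2g mN/m", object$gamma, object$gamma_sd))
}
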