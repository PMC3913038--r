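# broom-style tidy()/glance() methods for the package's fitted objects.

#' @export
tidy.bridge_fit <- function(x, ...) {
  tibble(term = c("tau", "lag", "plateau"),
         estimate = c(x$tau, x$lag, x$plateau),
         std.error = unname(x$se[c("tau", "lag", "plateau")]))
}

#' @export
glance.bridge_fit <- function(x, ...) {
  tibble(tau = x$tau, lag = x$lag, plateau = x$plateau,
         sigma = x$sigma, identifiable = x$identifiable,
         nobs = nrow(x$data))
}

#' @export
tidy.frap_fit <- function(x, ...) {
  terms <- names(coef(x$fit))
  tibble(term = terms, estimate = unname(coef(x$fit)),
         std.error = unname(x$se[terms]))
}

#' @export
glance.frap_fit <- function(x, ...) {
  tibble(D = x$D, beta = x$beta, immobile = x$immobile, w = x$w,
         sigma = x$sigma, nobs = nrow(x$data))
}

#' @export
tidy.tension_result <- function(x, ...) x$drops

#' @export
glance.tension_result <- function(x, ...) {
  tibble(gamma = x$gamma, gamma_sd = x$gamma_sd, n_drops = x$n,
         d_um = x$d_um, delta_rho = x$delta_rho)
}

#' @export
tidy.coloc_result <- function(x, ...) {
  tibble(n_a = x$n_a, n_exp = x$n_exp, s = x$s, n_s = x$n_s,
         tail_p = x$tail_p, verdict = x$verdict)
}

#' @export
tidy.coloc_summary <- function(x, ...) x$fields

#' @export
glance.coloc_summary <- function(x, ...) {
  tibble(n_fields = x$n_fields, mean_diff = x$mean_diff, statistic = x$t,
         p.value = x$p_value, verdict = x$verdict, alpha = x$alpha)
}

#' @export
tidy.connection_estimate <- function(x, ...) {
  tibble(tau_fit = x$tau_fit,
         tau_bulk_low = min(x$tau_bulk), tau_bulk_high = max(x$tau_bulk),
         n_c = x$n_c_point, n_c_low = x$n_c_range[1], n_c_high = x$n_c_range[2])
}

#' @export
glance.ld_size_summary <- function(x, ...) {
  tibble(n = x$n, mean = x$mean, median = x$median, sd = x$sd,
         n_modes = x$n_modes)
}

#' @export
tidy.ld_size_summary <- function(x, ...) x$modes
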