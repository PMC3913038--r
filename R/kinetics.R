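# Diffusion-limited kinetics of ER-to-LD protein targeting through membrane
# bridges.
#
# With the ER concentration C0 held constant, the flux through one bridge is
# J = k (C0 - N/S) with permeability k = D/l, so the LD-bound amount obeys
# dN/dt = n_c * k * L * (C0 - N/S) and saturates as
# N(t) = C0 S (1 - exp(-t/tau)) with tau = l S / (n_c D L). Comparing the
# fitted targeting time with the single-bridge "bulk" time
# tau_bulk = (l/L) * 4 pi R^2 / D gives the number of bridges
# n_c = tau_bulk / tau.

#' Closed-form targeting curve
#'
#' `N(t) = plateau * (1 - exp(-(t - lag)/tau))` for `t >= lag` and 0 before;
#' the solution of the constant-source, diffusion-limited bridge model with an
#' onset delay.
#'
#' @param t Time, minutes (vector).
#' @param tau Characteristic time, minutes (> 0).
#' @param lag Onset delay, minutes (>= 0).
#' @param plateau Saturation level `C0 * S`, arbitrary units.
#' @return Numeric vector `N(t)`.
#' @export
#' @examples
#' targeting_curve(c(5, 5 + 3.6, 1e6), tau = 3.6, lag = 5)  # 0, 1 - 1/e, 1
targeting_curve <- function(t, tau, lag = 0, plateau = 1) {
  check_scalar(tau, "tau", positive = TRUE)
  check_scalar(lag, "lag", nonneg = TRUE)
  plateau * (1 - exp(-pmax(t - lag, 0) / tau))
}

#' Fit the targeting model to a time course
#'
#' Nonlinear least squares (Levenberg-Marquardt) fit of
#' `plateau * (1 - exp(-(t - lag)/tau))` (zero before `lag`) to an observed
#' time course, with all three parameters free and bounded below at zero.
#' Standard errors come from the local linearization at the optimum. When the
#' curve has not plateaued within the record, `tau` is weakly identified:
#' this is flagged (`identifiable = FALSE` with a warning) rather than
#' treated as a failure.
#'
#' @param tc Data frame with columns `t` (minutes) and `intensity`, e.g. from
#'   [sim_timecourse()].
#' @param start Optional named list of starting values (`tau`, `lag`,
#'   `plateau`); by default derived from the data.
#' @return An object of class `bridge_fit`: list with `tau`, `lag`,
#'   `plateau`, `se` (named vector), `sigma` (residual SD), `identifiable`,
#'   `fit` (the underlying `nls` object) and `data`.
#' @export
#' @examples
#' tc <- sim_timecourse(tau = 3.6, lag = 5, noise_sd = 0.03, seed = 1)
#' fit_targeting(tc)
fit_targeting <- function(tc, start = NULL) {
  tc <- as_tibble(tc)
  if (!all(c("t", "intensity") %in% names(tc))) {
    abort("`tc` must have columns `t` and `intensity`.")
  }
  if (nrow(tc) < 6) abort("need >= 6 time points to fit (tau, lag, plateau).")
  check_increasing(tc$t, "tc$t")
  y <- tc$intensity; t <- tc$t
  if (is.null(start)) {
    plateau0 <- max(quantile(y, 0.95), 1e-6)
    above <- which(y > 0.1 * plateau0)
    lag0 <- if (length(above) > 0) max(min(t[above]) - diff(range(t)) / 20, 0) else 0
    hit63 <- which(y > 0.63 * plateau0)
    tau0 <- if (length(hit63) > 0) max(t[hit63[1]] - lag0, diff(range(t)) / 20)
            else diff(range(t)) / 2
    start <- list(tau = tau0, lag = lag0, plateau = plateau0)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      intensity ~ plateau * (1 - exp(-pmax(t - lag, 0) / tau)),
      data = tc, start = start,
      lower = c(tau = 1e-8, lag = 0, plateau = 1e-12),
      upper = c(tau = Inf, lag = max(t), plateau = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14)
    ),
    error = function(e) {
      abort(sprintf(
        "targeting fit did not converge: %s (residual SD of a flat model: %.3g)",
        conditionMessage(e), sd(y)
      ))
    }
  )
  cf <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) setNames(rep(NA_real_, 3), names(cf)))
  identifiable <- is.finite(se["tau"]) && se["tau"] <= cf["tau"]
  if (!identifiable) {
    warn(sprintf(
      "tau is weakly identified (tau = %.3g, SE = %.3g): the curve may not span the rise.",
      cf["tau"], se["tau"]
    ))
  }
  structure(
    list(tau = unname(cf["tau"]), lag = unname(cf["lag"]),
         plateau = unname(cf["plateau"]), se = se,
         sigma = summary(fit)$sigma, identifiable = identifiable,
         fit = fit, data = tc),
    class = "bridge_fit"
  )
}

#' @export
print.bridge_fit <- function(x, ...) {
  cat(sprintf(
    "<bridge_fit> tau = %.4g +/- %.2g min, lag = %.3g min, plateau = %.4g%s\n",
    x$tau, x$se["tau"], x$lag, x$plateau,
    if (!x$identifiable) " [tau weakly identified]" else ""
  ))
  invisible(x)
}

#' Geometry of an ER-LD connection
#'
#' Bundles the parameters of the bridge model: LD radius `R` (um), ER
#' diffusion coefficient `D` (um^2/s), the ratio `l_over_L` of the connection
#' length `l` to the section length `L` (dimensionless, typically 1.5-3), and
#' optionally `l` and `L` themselves (um; only their ratio enters the
#' characteristic times).
#'
#' @param R LD radius, um.
#' @param D Diffusion coefficient in the ER, um^2/s.
#' @param l_over_L Ratio `l / L`; ignored when both `l` and `L` are given.
#' @param l,L Connection length and section length, um (optional).
#' @return A list of class `geometry_params` with `R`, `D`, `l`, `L`,
#'   `l_over_L`, and `S = 4 pi R^2` (um^2).
#' @export
#' @examples
#' geometry_params(R = 1.4, D = 0.035)
geometry_params <- function(R, D = 0.035, l_over_L = 2, l = NULL, L = NULL) {
  check_scalar(R, "R", positive = TRUE)
  check_scalar(D, "D", positive = TRUE)
  if (!is.null(l) && !is.null(L)) {
    check_scalar(l, "l", positive = TRUE)
    check_scalar(L, "L", positive = TRUE)
    l_over_L <- l / L
  } else {
    check_scalar(l_over_L, "l_over_L", positive = TRUE)
    L <- L %||% 0.1            # a ~100 nm neck section; only l/L matters
    l <- l_over_L * L
  }
  structure(list(R = R, D = D, l = l, L = L, l_over_L = l_over_L,
                 S = 4 * pi * R^2),
            class = "geometry_params")
}

#' Single-connection bulk diffusion time
#'
#' The time for diffusion through one ER-LD connection to load the whole LD
#' surface: `tau_bulk = (l/L) * S / D = (l/L) * 4 pi R^2 / D`, returned in
#' minutes. With `l/L = 2` this is `8 pi R^2 / D`.
#'
#' @param g A [geometry_params()] object (or arguments forwarded to it).
#' @param ... Passed to [geometry_params()] when `g` is not already one.
#' @return `tau_bulk` in minutes.
#' @export
#' @examples
#' bulk_time(geometry_params(R = 1, D = 0.035))  # ~ 12 min
bulk_time <- function(g, ...) {
  if (!inherits(g, "geometry_params")) g <- geometry_params(g, ...)
  g$l_over_L * g$S / g$D / 60
}

#' Number of ER-LD connections from the fitted targeting time
#'
#' The bridge model gives `tau = l S / (n_c D L)`, so the number of
#' connections needed to reach the observed targeting speed is
#' `n_c = tau_bulk / tau_fit`, where `tau_bulk` is the single-connection bulk
#' time. Supplying a range of `tau_bulk` (e.g. from the spread of plausible
#' `R` and `D`) propagates to a range of `n_c`; supplying the fit's standard
#' error widens the range further.
#'
#' @param tau_fit Fitted targeting time in minutes, or a `bridge_fit` object.
#' @param tau_bulk Bulk time(s) in minutes: a scalar or a length-2 range.
#' @param tau_fit_se Optional standard error of `tau_fit` (taken from the
#'   `bridge_fit` when available). If `tau_fit_se >= tau_fit` the estimate is
#'   refused as unidentifiable.
#' @return An object of class `connection_estimate`: list with `tau_fit`,
#'   `tau_bulk` (sorted), `n_c_point` (`mean(tau_bulk) / tau_fit`) and
#'   `n_c_range`.
#' @export
#' @examples
#' estimate_connections(3.6, c(21, 31))  # ~ 5.8 - 8.6 connections
estimate_connections <- function(tau_fit, tau_bulk, tau_fit_se = NULL) {
  if (inherits(tau_fit, "bridge_fit")) {
    tau_fit_se <- tau_fit_se %||% unname(tau_fit$se["tau"])
    tau_fit <- tau_fit$tau
  }
  check_scalar(tau_fit, "tau_fit", positive = TRUE)
  if (!is.numeric(tau_bulk) || !length(tau_bulk) %in% 1:2 || any(tau_bulk <= 0)) {
    abort("`tau_bulk` must be one or two positive values (minutes).")
  }
  if (!is.null(tau_fit_se) && is.finite(tau_fit_se) && tau_fit_se >= tau_fit) {
    abort(sprintf(
      "tau_fit is not identifiable (estimate %.3g <= SE %.3g); refusing to convert to a connection count.",
      tau_fit, tau_fit_se
    ))
  }
  tb <- sort(tau_bulk)
  lo_tau <- tau_fit + (if (!is.null(tau_fit_se) && is.finite(tau_fit_se)) tau_fit_se else 0)
  hi_tau <- tau_fit - (if (!is.null(tau_fit_se) && is.finite(tau_fit_se)) tau_fit_se else 0)
  structure(
    list(tau_fit = tau_fit, tau_bulk = tb,
         n_c_point = mean(tb) / tau_fit,
         n_c_range = c(min(tb) / lo_tau, max(tb) / hi_tau)),
    class = "connection_estimate"
  )
}

#' @export
print.connection_estimate <- function(x, ...) {
  cat(sprintf(
    "<connection_estimate> tau_fit = %.3g min, tau_bulk = [%s] min -> n_c = %.2g (range %.2g - %.2g)\n",
    x$tau_fit, paste(format(x$tau_bulk, digits = 3), collapse = ", "),
    x$n_c_point, x$n_c_range[1], x$n_c_range[2]
  ))
  invisible(x)
}

#' Simulate protein flux onto an LD through n_c bridges
#'
#' Two routes to the targeting curve: `mode = "ode"` integrates
#' `dN/dt = n_c k L (C0 - N/S)` numerically (with `k = D/l`), and `mode =
#' "particle"` draws independent molecules whose first crossing of one of the
#' `n_c` absorbing bridges occurs at an exponential time with the model's bulk
#' rate, rescaling the arrived fraction to `N`. Both converge to
#' `N(t) = C0 S (1 - exp(-t/tau))` with `tau = l S / (n_c D L)`.
#'
#' @param n_c Number of connections (>= 0).
#' @param g A [geometry_params()] object.
#' @param C0 ER concentration (arbitrary units per um^2).
#' @param t Time grid, minutes.
#' @param mode `"ode"` or `"particle"`.
#' @param n_particles Number of molecules in particle mode.
#' @param seed Integer seed (particle mode) or `NULL`.
#' @return A tibble `(t, N)` with attribute `tau` (minutes; `Inf` when
#'   `n_c = 0`).
#' @export
#' @examples
#' g <- geometry_params(R = 1, D = 0.035)
#' sim <- simulate_flux(6, g, t = seq(0, 10, 0.5))
#' attr(sim, "tau")
simulate_flux <- function(n_c, g, C0 = 1, t = seq(0, 30, by = 0.5),
                          mode = c("ode", "particle"), n_particles = 2000,
                          seed = NULL) {
  mode <- match.arg(mode)
  check_scalar(n_c, "n_c", nonneg = TRUE)
  if (!inherits(g, "geometry_params")) abort("`g` must be a geometry_params object.")
  check_increasing(t, "t")
  if (any(t < 0)) abort("`t` must be >= 0.")
  tau_min <- if (n_c > 0) g$l * g$S / (n_c * g$D * g$L) / 60 else Inf
  if (n_c == 0) {
    return(structure(tibble(t = t, N = 0 * t), tau = Inf, mode = mode))
  }
  N <- switch(mode,
    ode = {
      k <- g$D / g$l                      # um/s
      rate <- n_c * k * g$L * 60          # per-minute flux coefficient
      rhs <- function(tt, y, parms) {
        list(rate * (C0 - y[1] / g$S))
      }
      times <- unique(c(0, t))
      sol <- deSolve::ode(y = c(N = 0), times = times, func = rhs, parms = NULL,
                          rtol = 1e-10, atol = 1e-12)
      if (attr(sol, "istate")[1] < 0) {
        abort(sprintf(
          "ODE integration failed; try a finer time grid (current spacing %.3g min).",
          min(diff(t))
        ))
      }
      sol[match(t, times), "N"]
    },
    particle = with_seed(seed, {
      arrivals <- rexp(n_particles, rate = 1 / tau_min)
      vapply(t, function(tt) mean(arrivals <= tt), numeric(1)) * C0 * g$S
    })
  )
  structure(tibble(t = t, N = N), tau = tau_min, mode = mode)
}
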