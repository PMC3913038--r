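# FRAP on ER tubules: apparent diffusion coefficient from the recovery of a
# rectangular bleach on an effectively one-dimensional, infinite tubule.

#' Closed-form 1-D FRAP recovery at the bleach centre
#'
#' Solution of the 1-D diffusion equation for a rectangular bleach of width
#' `w` and depth `beta` on an infinite line, evaluated at the bleach centre:
#' `F(t) = 1 - beta * erf(w / (4 * sqrt(D * t)))`, with `F(0) = 1 - beta` and
#' `F -> 1` as `t -> Inf` (single mobile pool). An optional immobile fraction
#' leaves `immobile * beta` of the deficit unrecovered.
#'
#' @param t Time after bleach, seconds (>= 0).
#' @param D Diffusion coefficient, um^2/s.
#' @param w Bleach width, um.
#' @param beta Bleach depth in `(0, 1]`.
#' @param immobile Immobile fraction in `[0, 1)` (default 0).
#' @return Normalized intensity at the bleach centre.
#' @export
#' @examples
#' frap_recovery(c(0, 1e9), D = 0.035, w = 2, beta = 0.8)  # 0.2, ~1
frap_recovery <- function(t, D, w, beta, immobile = 0) {
  check_scalar(D, "D", positive = TRUE)
  check_scalar(w, "w", positive = TRUE)
  check_scalar(beta, "beta", lower = 1e-12, upper = 1)
  check_scalar(immobile, "immobile", lower = 0, upper = 1 - 1e-12)
  arg <- ifelse(t > 0, w / (4 * sqrt(D * t)), Inf)
  rec <- 1 - erf(arg)                 # recovered share of the deficit
  1 - beta + beta * (1 - immobile) * rec
}

#' Fit the apparent diffusion coefficient from a FRAP curve
#'
#' Least-squares fit of the 1-D rectangular-bleach recovery model (see
#' [frap_recovery()]) to a normalized centre-of-bleach recovery curve. The
#' bleach width must be known from the experiment geometry; the bleach depth
#' is fitted by default (or fixed via `beta`). An optional immobile fraction
#' can be fitted with `fit_immobile = TRUE`.
#'
#' @param curve Data frame with columns `t` (seconds) and `intensity`
#'   (normalized, pre-bleach = 1), e.g. from [sim_frap_curve()] or
#'   [simulate_frap_fd()].
#' @param w Bleach width, um (defaults to the curve's `w` attribute).
#' @param beta Fixed bleach depth, or `NULL` to fit it.
#' @param fit_immobile Also fit an immobile fraction (default `FALSE`, i.e.
#'   full recovery).
#' @return An object of class `frap_fit`: list with `D`, `se` (named), `beta`,
#'   `immobile`, `sigma`, `fit`, `data`.
#' @export
#' @examples
#' fr <- sim_frap_curve(D = 0.035, noise_sd = 0.01, seed = 1)
#' fit_frap(fr)
fit_frap <- function(curve, w = attr(curve, "w"), beta = NULL,
                     fit_immobile = FALSE) {
  curve <- as_tibble(curve)
  if (!all(c("t", "intensity") %in% names(curve))) {
    abort("`curve` must have columns `t` and `intensity`.")
  }
  if (is.null(w)) abort("bleach width `w` must be supplied (geometry of the experiment).")
  check_scalar(w, "w", positive = TRUE)
  post <- curve[curve$t >= 0, ]
  if (nrow(post) < 8) abort("need >= 8 post-bleach points to fit D.")
  y <- post$intensity
  f0 <- y[which.min(post$t)]
  recovered <- (max(y) - f0) / max(1 - f0, 1e-12)
  if (recovered < 0.10) {
    abort(sprintf(
      "insufficient recovery over the record (%.1f%% of the bleached deficit); cannot estimate D.",
      100 * recovered
    ))
  }
  beta0 <- min(max(1 - f0, 0.05), 0.999)
  # time at half recovery gives a diffusive starting guess: erf(x) = 0.5 at
  # x ~ 0.4769, so D0 ~ (w / (4 * 0.4769))^2 / t_half
  half <- post$t[which(y >= f0 + 0.5 * (1 - f0))[1]]
  D0 <- if (is.finite(half) && !is.na(half) && half > 0) {
    (w / (4 * 0.4769))^2 / half
  } else 0.01
  model <- function(t, D, beta, immobile) frap_recovery(t, D, w, beta, immobile)
  fit <- tryCatch(
    {
      if (is.null(beta) && fit_immobile) {
        minpack.lm::nlsLM(intensity ~ model(t, D, beta, immobile), data = post,
                          start = list(D = D0, beta = beta0, immobile = 0.01),
                          lower = c(D = 1e-10, beta = 1e-6, immobile = 0),
                          upper = c(D = Inf, beta = 1, immobile = 0.999))
      } else if (is.null(beta)) {
        minpack.lm::nlsLM(intensity ~ model(t, D, beta, 0), data = post,
                          start = list(D = D0, beta = beta0),
                          lower = c(D = 1e-10, beta = 1e-6),
                          upper = c(D = Inf, beta = 1))
      } else {
        check_scalar(beta, "beta", lower = 1e-12, upper = 1)
        minpack.lm::nlsLM(intensity ~ model(t, D, beta, 0), data = post,
                          start = list(D = D0), lower = c(D = 1e-10))
      }
    },
    error = function(e) {
      abort(sprintf("FRAP fit did not converge: %s (n = %d points, starting D = %.3g um^2/s)",
                    conditionMessage(e), nrow(post), D0))
    }
  )
  cf <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) setNames(rep(NA_real_, length(cf)), names(cf)))
  structure(
    list(D = unname(cf["D"]), se = se,
         beta = if ("beta" %in% names(cf)) unname(cf["beta"]) else beta,
         immobile = if ("immobile" %in% names(cf)) unname(cf["immobile"]) else 0,
         w = w, sigma = summary(fit)$sigma, fit = fit, data = post),
    class = "frap_fit"
  )
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf("<frap_fit> D = %.4g +/- %.2g um^2/s (w = %g um, beta = %.3g, immobile = %.3g)\n",
              x$D, x$se["D"], x$w, x$beta, x$immobile))
  invisible(x)
}

#' Finite-difference FRAP simulation (independent numerical oracle)
#'
#' Explicit finite-difference integration of the 1-D diffusion equation on a
#' long reflecting domain, starting from a rectangular bleach of width `w`
#' and depth `beta` centred at 0, sampled at the bleach centre. This shares no
#' code with the closed form in [frap_recovery()] and is used to validate the
#' fitting route against a purely numerical solution of the same physics.
#'
#' @param t Sampling times, seconds (>= 0), strictly increasing.
#' @param D Diffusion coefficient, um^2/s.
#' @param w Bleach width, um.
#' @param beta Bleach depth in `(0, 1]`.
#' @param dx Grid spacing, um.
#' @param domain Total domain length, um (must stay large compared with the
#'   diffusion length `sqrt(2 D t_max)` so the line is effectively infinite).
#' @return A tibble `(t, intensity)` with attributes `D`, `w`, `beta`.
#' @export
#' @examples
#' fd <- simulate_frap_fd(t = seq(0, 60, 2), D = 0.035, w = 2, beta = 0.8)
#' fit_frap(fd)$D
simulate_frap_fd <- function(t, D, w, beta, dx = 0.05, domain = 40) {
  check_increasing(t, "t")
  if (any(t < 0)) abort("`t` must be >= 0.")
  check_scalar(D, "D", positive = TRUE)
  check_scalar(w, "w", positive = TRUE)
  check_scalar(beta, "beta", lower = 1e-12, upper = 1)
  check_scalar(dx, "dx", positive = TRUE)
  check_scalar(domain, "domain", positive = TRUE)
  n <- max(3L, round(domain / dx))
  if (n %% 2L == 0L) n <- n + 1L            # odd count puts a node at x = 0
  x <- (seq_len(n) - (n + 1) / 2) * dx      # centred grid
  # partial-coverage initial condition at the bleach edges
  covered <- pmin(pmax((w / 2 - abs(x)) / dx + 0.5, 0), 1)
  c0 <- 1 - beta * covered
  t_max <- max(t)
  dt <- dx^2 / (4 * D)                      # half the FTCS stability limit
  n_steps <- if (t_max > 0) ceiling(t_max / dt) else 0L
  dt <- if (n_steps > 0) t_max / n_steps else dt
  lam <- D * dt / dx^2
  centre <- which.min(abs(x))
  out <- numeric(length(t))
  step_of <- round(t / dt)
  out[step_of == 0] <- c0[centre]
  u <- c0
  if (n_steps > 0) {
    for (s in seq_len(n_steps)) {
      u_l <- c(u[1], u[-n])                 # reflecting boundaries
      u_r <- c(u[-1], u[n])
      u <- u + lam * (u_l - 2 * u + u_r)
      hit <- which(step_of == s)
      if (length(hit) > 0) out[hit] <- u[centre]
    }
  }
  structure(tibble(t = t, intensity = out), D = D, w = w, beta = beta)
}
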