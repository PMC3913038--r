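# Drop-weight (drop-volume) tensiometry.
#
# gamma = m * g / (pi * d * f): the weight of the detached drop balances the
# vertical surface-tension force around the tube mouth, corrected by the
# empirical Harkins-Brown factor f, which accounts for the fraction of the
# pendant drop that actually falls.

# Classical Harkins-Brown correction table, F as a function of x = r / V^(1/3)
# (tube radius over cube root of detached drop volume). Values from the
# classical drop-weight calibration (Harkins & Brown 1919, as reproduced in
# standard surface-chemistry references, e.g. Adamson & Gast, Physical
# Chemistry of Surfaces).
hb_table <- list(
  x = c(0.30, 0.35, 0.40, 0.45, 0.50, 0.55, 0.60, 0.65, 0.70, 0.75,
        0.80, 0.85, 0.90, 0.95, 1.00, 1.05, 1.10, 1.15, 1.20),
  f = c(0.7256, 0.7011, 0.6828, 0.6669, 0.6515, 0.6362, 0.6250, 0.6171,
        0.6093, 0.6032, 0.6000, 0.5992, 0.5998, 0.6034, 0.6098, 0.6179,
        0.6280, 0.6407, 0.6535)
)

# geometric constant linking the two ratio conventions:
# x = r/V^(1/3) = (r/r_drop) * (3/(4*pi))^(1/3)
hb_geom <- (3 / (4 * pi))^(1 / 3)

# Interpolators, built once. The table has a minimum near x = 0.85; each
# monotone branch gets a shape-preserving (Hyman) cubic. Below the classical
# table (x < 0.30, i.e. drops much larger than the tube — the regime of
# low-tension oil/water interfaces on fine tubes) the curve is extended by the
# same monotone interpolation anchored at the thin-tip limit f(0) = 1, where
# the whole ideal drop detaches. Values in (0, 0.30) are therefore an
# approximate extension, not measured calibration points.
hb_fun_dec <- splinefun(c(0, hb_table$x[hb_table$x <= 0.85]),
                        c(1, hb_table$f[hb_table$x <= 0.85]),
                        method = "hyman")
hb_fun_inc <- splinefun(hb_table$x[hb_table$x >= 0.85],
                        hb_table$f[hb_table$x >= 0.85],
                        method = "hyman")

hb_x_range <- function() c(0, 1.20)
hb_max_ratio <- function() hb_x_range()[2] / hb_geom  # largest r_tube/r_drop

#' Harkins-Brown geometric correction factor
#'
#' Empirical correction for drop-weight tensiometry: only a fraction `f` of
#' the ideal (Tate) drop detaches, so `gamma = m*g / (pi*d*f)`. The factor
#' depends on the ratio of the tube radius to the radius of the detached drop
#' (equivalently on `r / V^(1/3)`). The classical calibration covers
#' `r / V^(1/3)` in `[0.30, 1.20]`; below that (large drops on fine tubes,
#' typical for low interfacial tensions) the package uses a monotone cubic
#' extension anchored at the thin-tip limit `f -> 1`, documented as
#' approximate. Ratios above the tabulated range raise an error.
#'
#' @param ratio Tube radius divided by detached-drop radius
#'   `r_drop = (3 v / (4 pi))^(1/3)`; must be in `(0, 1.934]`.
#' @return The correction factor `f` (dimensionless, in `(0.59, 1]`).
#' @export
#' @examples
#' harkins_brown(0.80 / (3 / (4 * pi))^(1/3))  # table node x = 0.80 -> 0.6000
#' harkins_brown(0.1)                          # thin-tip extension, near 1
harkins_brown <- function(ratio) {
  if (!is.numeric(ratio) || anyNA(ratio)) abort("`ratio` must be numeric.")
  x <- ratio * hb_geom
  rng <- hb_x_range()
  if (any(ratio <= 0) || any(x > rng[2] + 1e-12)) {
    abort(sprintf(
      "ratio outside the Harkins-Brown domain: need r_tube/r_drop in (0, %.3f] (r/V^(1/3) <= %.2f).",
      hb_max_ratio(), rng[2]
    ))
  }
  x <- pmin(x, rng[2])
  ifelse(x <= 0.85, hb_fun_dec(x), hb_fun_inc(x))
}

#' Interfacial tension from a drop-weight detachment series
#'
#' For each detached drop, the mass is `m = v * delta_rho` and the per-drop
#' tension is `gamma_i = m_i * g / (pi * d * f_i)`, with the Harkins-Brown
#' factor `f_i` evaluated at the drop's own volume (the factor depends on the
#' ratio of the tube radius to the detached-drop radius, both of which follow
#' directly from `d` and `v_i`). The result is the mean and SD over drops.
#'
#' @param series Data frame with a `volume_ul` column (drop detachment volume
#'   in microlitres), e.g. from [sim_drop_series()].
#' @param d_um Tube inner diameter, um (default taken from the series
#'   attribute; 250 um is the classical fine-tube setup).
#' @param delta_rho Density difference, kg/m^3 (attribute fallback).
#' @param g Gravitational acceleration, m/s^2.
#' @param f Optional fixed correction factor overriding the Harkins-Brown
#'   evaluation (e.g. `f = 1` for the ideal Tate law).
#' @return An object of class `tension_result`: list with `gamma` (mean,
#'   mN/m), `gamma_sd`, `n`, and `drops`, a tibble of per-drop `volume_ul`,
#'   `mass_mg`, `ratio`, `f`, `gamma_mN_m`.
#' @export
#' @examples
#' s <- sim_drop_series(gamma = 30, n_drops = 15, noise_frac = 0.01, seed = 2)
#' surface_tension(s)
surface_tension <- function(series, d_um = attr(series, "d_um"),
                            delta_rho = attr(series, "delta_rho"),
                            g = 9.80665, f = NULL) {
  series <- as_tibble(series)
  if (!"volume_ul" %in% names(series) || nrow(series) < 1) {
    abort("`series` must have >= 1 row and a `volume_ul` column.")
  }
  if (is.null(d_um) || is.null(delta_rho)) {
    abort("`d_um` and `delta_rho` must be supplied (or present as series attributes).")
  }
  check_scalar(d_um, "d_um", positive = TRUE)
  check_scalar(delta_rho, "delta_rho", positive = TRUE)
  v <- series$volume_ul * 1e-9                 # m^3
  if (any(!is.finite(v) | v <= 0)) abort("all drop volumes must be positive.")
  d_m <- d_um * 1e-6
  ratio <- hb_ratio(v, d_m)
  fi <- if (is.null(f)) harkins_brown(ratio) else rep_len(f, length(v))
  m <- v * delta_rho                           # kg
  gam <- m * g / (pi * d_m * fi) * 1e3         # mN/m
  drops <- tibble(volume_ul = series$volume_ul, mass_mg = m * 1e6,
                  ratio = ratio, f = fi, gamma_mN_m = gam)
  structure(
    list(gamma = mean(gam), gamma_sd = if (length(gam) > 1) sd(gam) else NA_real_,
         n = length(gam), d_um = d_um, delta_rho = delta_rho, drops = drops),
    class = "tension_result"
  )
}

#' @export
print.tension_result <- function(x, ...) {
  cat(sprintf("<tension_result> gamma = %.4g +/- %.2g mN/m (n = %d drops, d = %g um)\n",
              x$gamma, x$gamma_sd, x$n, x$d_um))
  invisible(x)
}
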