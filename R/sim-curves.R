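#' Simulate an ER-to-LD targeting time course
#'
#' Saturating-exponential accumulation of an ER protein on an LD after the
#' targeting machinery becomes available (e.g. after cell-cell fusion):
#' signal is zero during a lag phase, then rises as
#' `plateau * (1 - exp(-(t - lag)/tau))`, with optional additive Gaussian
#' noise. The default characteristic time `tau = 3.6` min matches the
#' experimentally observed GPAT4 targeting time; lag phases of 1-25 min are
#' typical.
#'
#' @param t Time grid in minutes, strictly increasing.
#' @param tau Characteristic targeting time, minutes (> 0).
#' @param lag Lag before targeting starts, minutes (>= 0).
#' @param plateau Saturation level `C0 * S`, arbitrary units.
#' @param noise_sd Additive Gaussian noise SD, same units as `plateau`.
#' @param seed Integer seed or `NULL`.
#' @return A tibble `(t, intensity)` with attributes `tau`, `lag`, `plateau`.
#' @export
#' @examples
#' tc <- sim_timecourse(seed = 1, noise_sd = 0.02)
#' head(tc)
sim_timecourse <- function(t = seq(0, 30, by = 0.5), tau = 3.6, lag = 5,
                           plateau = 1, noise_sd = 0, seed = NULL) {
  check_increasing(t, "t")
  check_scalar(tau, "tau", positive = TRUE)
  check_scalar(lag, "lag", nonneg = TRUE)
  check_scalar(plateau, "plateau", positive = TRUE)
  check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  with_seed(seed, {
    y <- targeting_curve(t, tau = tau, lag = lag, plateau = plateau)
    if (noise_sd > 0) y <- y + rnorm(length(t), sd = noise_sd)
    structure(tibble(t = t, intensity = y),
              tau = tau, lag = lag, plateau = plateau, noise_sd = noise_sd)
  })
}

#' Simulate a 1-D tubule FRAP recovery curve
#'
#' Normalized centre-of-bleach intensity for pure diffusion on an effectively
#' infinite tubule after a rectangular bleach of width `w` and depth `beta`:
#' `F(t) = 1 - beta * erf(w / (4 * sqrt(D * t)))` (see [frap_recovery()]).
#' The default `D = 0.035` um^2/s is the magnitude measured for GPAT4 in the
#' ER.
#'
#' @param t Time grid in seconds (>= 0), strictly increasing.
#' @param D Diffusion coefficient, um^2/s.
#' @param w Bleach width, um.
#' @param beta Bleach depth, fraction of pre-bleach intensity in `(0, 1]`.
#' @param noise_sd Additive Gaussian noise SD (normalized units).
#' @param seed Integer seed or `NULL`.
#' @return A tibble `(t, intensity)` with attributes `D`, `w`, `beta`.
#' @export
#' @examples
#' fr <- sim_frap_curve(D = 0.035, seed = 1)
#' fr$intensity[1]  # = 1 - beta at t = 0
sim_frap_curve <- function(t = seq(0, 120, by = 1), D = 0.035, w = 2,
                           beta = 0.8, noise_sd = 0, seed = NULL) {
  check_increasing(t, "t")
  if (any(t < 0)) abort("`t` must be >= 0.")
  check_scalar(D, "D", positive = TRUE)
  check_scalar(w, "w", positive = TRUE)
  check_scalar(beta, "beta", lower = 1e-12, upper = 1)
  check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  with_seed(seed, {
    y <- frap_recovery(t, D = D, w = w, beta = beta)
    if (noise_sd > 0) y <- y + rnorm(length(t), sd = noise_sd)
    structure(tibble(t = t, intensity = y), D = D, w = w, beta = beta)
  })
}

#' Simulate a drop-weight detachment series
#'
#' Generates per-drop detachment volumes for drop-weight (drop-volume)
#' tensiometry. The quasi-static detachment volume `v` solves the force
#' balance `v * delta_rho * g = gamma * pi * d * f` self-consistently, where
#' the Harkins-Brown factor `f` itself depends on `v` through the detached
#' drop radius; the root is found numerically and multiplicative noise is
#' applied per drop. Defaults describe a buffer drop forming in a
#' triacylglycerol oil phase from a 250-um tube at a phospholipid-covered
#' interfacial tension of a few mN/m.
#'
#' @param gamma Interfacial tension, mN/m.
#' @param d Tube inner diameter, um.
#' @param delta_rho Density difference between the phases, kg/m^3.
#' @param n_drops Number of drops.
#' @param noise_frac SD of the multiplicative volume noise (fraction).
#' @param g Gravitational acceleration, m/s^2.
#' @param seed Integer seed or `NULL`.
#' @return A tibble `(drop, volume_ul)` with attributes `d_um`, `delta_rho`,
#'   `g`, `gamma_true` (mN/m) ready for [surface_tension()].
#' @export
#' @examples
#' s <- sim_drop_series(gamma = 2, n_drops = 5, seed = 1)
#' surface_tension(s)$gamma
sim_drop_series <- function(gamma = 2, d = 250, delta_rho = 85, n_drops = 15,
                            noise_frac = 0, g = 9.80665, seed = NULL) {
  check_scalar(gamma, "gamma", positive = TRUE)
  check_scalar(d, "d", positive = TRUE)
  check_scalar(delta_rho, "delta_rho", positive = TRUE)
  check_scalar(n_drops, "n_drops", positive = TRUE)
  check_scalar(noise_frac, "noise_frac", nonneg = TRUE)
  with_seed(seed, {
    v <- detachment_volume(gamma, d, delta_rho, g)  # m^3
    vol <- rep(v, n_drops)
    if (noise_frac > 0) vol <- vol * (1 + rnorm(n_drops, sd = noise_frac))
    if (any(vol <= 0)) abort("noise produced a non-positive drop volume; lower `noise_frac`.")
    structure(tibble(drop = seq_len(n_drops), volume_ul = vol * 1e9),
              d_um = d, delta_rho = delta_rho, g = g, gamma_true = gamma)
  })
}

# Solve v * delta_rho * g = gamma_Nm * pi * d_m * f(ratio(v)) for v (m^3).
detachment_volume <- function(gamma_mNm, d_um, delta_rho, g) {
  gamma <- gamma_mNm * 1e-3
  d_m <- d_um * 1e-6
  imbalance <- function(v) {
    f <- harkins_brown(hb_ratio(v, d_m))
    v * delta_rho * g - gamma * pi * d_m * f
  }
  # bracket by the ideal (f = 1) volume scaled across the admissible f range
  v1 <- gamma * pi * d_m / (delta_rho * g)
  lo <- 0.5 * v1
  hi <- 1.1 * v1
  # keep the bracket inside the correction's tabulated domain
  v_min_table <- (4 * pi / 3) * ((d_m / 2) / hb_max_ratio())^3
  lo <- max(lo, v_min_table * (1 + 1e-9))
  if (lo >= hi) {
    abort("requested gamma/d/delta_rho put the drop outside the Harkins-Brown domain.")
  }
  flo <- tryCatch(imbalance(lo), error = function(e) NA_real_)
  fhi <- tryCatch(imbalance(hi), error = function(e) NA_real_)
  if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0) {
    abort(paste0(
      "no self-consistent detachment volume in the bracket ",
      sprintf("[%.3g, %.3g] m^3; ", lo, hi),
      "gamma, d and delta_rho put the drop outside the Harkins-Brown domain."
    ))
  }
  uniroot(imbalance, c(lo, hi), tol = v1 * 1e-12)$root
}

# ratio r_tube / r_drop for a detached volume v (both in metres / m^3)
hb_ratio <- function(v, d_m) (d_m / 2) / ((3 * v / (4 * pi))^(1 / 3))

#' Simulate an LD diameter population
#'
#' Draws LD diameters (micrometres) from one of three phenotypes seen in
#' cultured cells: `"bimodal"` (many small LDs below a micrometre plus a few
#' large expanding LDs of several micrometres, the control phenotype),
#' `"monodisperse"` (a narrow unimodal population of intermediate size, mean
#' about 1.3 um, the Arf1/COPI-depletion phenotype), and `"giant"` (a
#' heavy-tailed population of enlarged LDs).
#'
#' @param mode One of `"bimodal"`, `"monodisperse"`, `"giant"`.
#' @param n Number of diameters to draw (>= 1).
#' @param params Optional list overriding the mode's default parameters:
#'   `monodisperse`: `mean_um`, `sdlog`; `bimodal`: `weight_small`,
#'   `meanlog_small`, `sdlog_small`, `meanlog_large`, `sdlog_large`;
#'   `giant`: `meanlog`, `sdlog`.
#' @param seed Integer seed or `NULL`.
#' @return Numeric vector of diameters (um) with attribute `mode`.
#' @export
#' @examples
#' d <- sim_size_population("monodisperse", n = 1000, seed = 1)
#' mean(d)  # close to 1.3
sim_size_population <- function(mode = c("bimodal", "monodisperse", "giant"),
                                n = 500, params = list(), seed = NULL) {
  if (!is.character(mode) || !mode[1] %in% c("bimodal", "monodisperse", "giant")) {
    abort("`mode` must be one of 'bimodal', 'monodisperse', 'giant'.")
  }
  mode <- mode[1]
  check_scalar(n, "n", lower = 1)
  defaults <- switch(mode,
    monodisperse = list(mean_um = 1.3, sdlog = 0.15),
    bimodal = list(weight_small = 0.75, meanlog_small = log(0.4),
                   sdlog_small = 0.25, meanlog_large = log(3.5),
                   sdlog_large = 0.2),
    giant = list(meanlog = log(1.8), sdlog = 0.5)
  )
  p <- utils::modifyList(defaults, params)
  with_seed(seed, {
    x <- switch(mode,
      monodisperse = rlnorm(n, meanlog = log(p$mean_um) - p$sdlog^2 / 2,
                            sdlog = p$sdlog),
      bimodal = {
        small <- runif(n) < p$weight_small
        ifelse(small,
               rlnorm(n, p$meanlog_small, p$sdlog_small),
               rlnorm(n, p$meanlog_large, p$sdlog_large))
      },
      giant = rlnorm(n, p$meanlog, p$sdlog)
    )
    structure(x, mode = mode)
  })
}
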