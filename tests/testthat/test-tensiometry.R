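# Drop-weight tensiometry: the Harkins-Brown correction and the
# generator-analyzer round trip.

hb_c <- (3 / (4 * pi))^(1 / 3)  # converts r/V^(1/3) to r_tube/r_drop

test_that("correction factor reproduces table nodes and stays between them", {
  # classical nodes (x = r/V^(1/3)): exact interpolation identities
  expect_equal(harkins_brown(0.30 / hb_c), 0.7256)
  expect_equal(harkins_brown(0.60 / hb_c), 0.6250)
  expect_equal(harkins_brown(0.85 / hb_c), 0.5992)
  expect_equal(harkins_brown(1.20 / hb_c), 0.6535)
  # midpoints lie between neighbouring node values (monotone interpolation)
  mid <- harkins_brown(0.325 / hb_c)
  expect_true(mid > 0.7011 && mid < 0.7256)
  mid2 <- harkins_brown(1.175 / hb_c)
  expect_true(mid2 > 0.6407 && mid2 < 0.6535)
  # thin-tip extension: approaches the Tate limit from below, monotonically
  xs <- seq(0.01, 0.30, 0.01) / hb_c
  fs <- harkins_brown(xs)
  expect_true(all(diff(fs) < 0))
  expect_true(all(fs <= 1 & fs > 0.7256 - 1e-9))
  # out-of-domain ratios name the valid range
  expect_error(harkins_brown(2.5), "0, 1.934")
  expect_error(harkins_brown(-1), "Harkins-Brown")
})

test_that("generator and analyzer invert each other", {
  # noiseless: exact round trip
  s <- sim_drop_series(gamma = 30, d = 250, delta_rho = 85, n_drops = 5,
                       noise_frac = 0)
  expect_equal(surface_tension(s)$gamma, 30, tolerance = 1e-6)
  # 1% volume noise, 15 drops: mean within 2%, SD reported
  s2 <- sim_drop_series(gamma = 30, d = 250, delta_rho = 85, n_drops = 15,
                        noise_frac = 0.01, seed = 2)
  r2 <- surface_tension(s2)
  expect_lt(abs(r2$gamma - 30) / 30, 0.02)
  expect_true(is.finite(r2$gamma_sd) && r2$gamma_sd > 0)
  expect_equal(r2$n, 15)
})

test_that("the ideal-law case matches hand arithmetic", {
  # f = 1, m = 1 mg, d = 250 um: gamma = m g / (pi d) = 12.49 mN/m
  v_ul <- 1e-6 / 85 * 1e9  # volume of a 1 mg drop at delta_rho = 85 kg/m^3
  r <- surface_tension(data.frame(volume_ul = v_ul), d_um = 250,
                       delta_rho = 85, f = 1)
  expect_equal(r$gamma, 1e-6 * 9.80665 / (pi * 250e-6) * 1e3, tolerance = 1e-12)
  expect_equal(round(r$gamma, 2), 12.49)
})

test_that("gamma is linear in drop mass at fixed d and f", {
  base <- data.frame(volume_ul = c(0.9, 1, 1.1))
  a <- surface_tension(base, d_um = 250, delta_rho = 100, f = 0.9)
  b <- surface_tension(base, d_um = 250, delta_rho = 200, f = 0.9)
  expect_equal(b$gamma, 2 * a$gamma)
  # and strictly increasing in mass
  heavier <- surface_tension(data.frame(volume_ul = base$volume_ul * 1.5),
                             d_um = 250, delta_rho = 100, f = 0.9)
  expect_gt(heavier$gamma, a$gamma)
})

test_that("infeasible geometry is reported, not silently extrapolated", {
  # gamma so small that the drop would fall outside the tabulated domain
  expect_error(sim_drop_series(gamma = 1e-6, d = 250, delta_rho = 85),
               "Harkins-Brown|bracket")
  expect_error(surface_tension(data.frame(volume_ul = 1e-9), d_um = 250,
                               delta_rho = 85), "Harkins-Brown")
})
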