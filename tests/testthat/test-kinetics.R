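# Bridge kinetics: closed form, parameter recovery, bulk time, connection
# counts, and the ODE / particle flux simulators against the closed form.

test_that("closed-form targeting curve has the right limits", {
  expect_equal(targeting_curve(5, tau = 3.6, lag = 5), 0)
  expect_equal(targeting_curve(5 + 3.6, tau = 3.6, lag = 5, plateau = 2),
               2 * (1 - exp(-1)))
  expect_equal(targeting_curve(1e9, tau = 3.6, lag = 5, plateau = 2), 2)
  # monotone non-decreasing and bounded by the plateau
  y <- targeting_curve(seq(0, 50, 0.1), tau = 2.5, lag = 3, plateau = 1.7)
  expect_true(all(diff(y) >= 0))
  expect_true(all(y <= 1.7 + 1e-12))
})

test_that("noiseless fits recover the generating parameters exactly", {
  tc <- sim_timecourse(t = seq(0, 30, 0.5), tau = 3.6, lag = 5, plateau = 1,
                       noise_sd = 0)
  f <- fit_targeting(tc)
  expect_equal(f$tau, 3.6, tolerance = 1e-6)
  expect_equal(f$lag, 5, tolerance = 1e-6)
  expect_equal(f$plateau, 1, tolerance = 1e-6)
  expect_true(f$identifiable)
})

test_that("mean tau over nine noisy fusion-like curves is within 10%", {
  set.seed(5)
  taus <- vapply(1:9, function(i) {
    tc <- sim_timecourse(t = seq(0, 60, 0.5), tau = 3.6,
                         lag = runif(1, 1, 25), plateau = 1, noise_sd = 0.05)
    fit_targeting(tc)$tau
  }, numeric(1))
  expect_lt(abs(mean(taus) - 3.6) / 3.6, 0.10)
})

test_that("a record ending mid-rise gives a wide-SE flag, not a rejection", {
  set.seed(42)
  tc <- sim_timecourse(t = seq(0, 1.8, 0.15), tau = 3.6, lag = 0, plateau = 1,
                       noise_sd = 0.05)
  f <- fit_targeting(tc)
  expect_gt(f$se["tau"] / f$tau, 0.3)  # poorly constrained, but reported
  expect_error(fit_targeting(tc[1:4, ]), ">= 6")
})

test_that("bulk time follows (l/L) * 4 pi R^2 / D", {
  g <- geometry_params(R = 1, D = 0.035, l_over_L = 2)
  expect_equal(bulk_time(g), 8 * pi / 0.035 / 60, tolerance = 1e-12)  # ~12 min
  # inverse in D, linear in l/L
  expect_equal(bulk_time(geometry_params(R = 1, D = 0.07, l_over_L = 2)),
               bulk_time(g) / 2)
  expect_equal(bulk_time(geometry_params(R = 1, D = 0.035, l_over_L = 3)) /
                 bulk_time(geometry_params(R = 1, D = 0.035, l_over_L = 1.5)), 2)
})

test_that("connection counts are tau_bulk / tau_fit with propagated ranges", {
  expect_equal(estimate_connections(3.6, 21)$n_c_point, 21 / 3.6)   # ~5.8
  expect_equal(estimate_connections(3.6, 31)$n_c_point, 31 / 3.6)   # ~8.6
  expect_equal(estimate_connections(4, 4)$n_c_point, 1)
  est <- estimate_connections(3.6, c(21, 31))
  expect_equal(est$n_c_range, c(21, 31) / 3.6)
  # strictly decreasing in tau_fit at fixed tau_bulk
  ncs <- vapply(seq(1, 10, 0.5), function(tf) {
    estimate_connections(tf, 21)$n_c_point
  }, numeric(1))
  expect_true(all(diff(ncs) < 0))
  expect_error(estimate_connections(2, 21, tau_fit_se = 3), "identifiable")
})

test_that("ODE flux matches the closed form at tight tolerance", {
  set.seed(17)
  for (i in 1:5) {
    g <- geometry_params(R = runif(1, 0.5, 3), D = runif(1, 0.01, 0.1),
                         l_over_L = runif(1, 1.5, 3))
    n_c <- sample(1:12, 1)
    C0 <- runif(1, 0.5, 2)
    t <- seq(0, runif(1, 10, 40), length.out = 40)
    sim <- simulate_flux(n_c, g, C0 = C0, t = t)
    tau <- g$l * g$S / (n_c * g$D * g$L) / 60
    expect_equal(attr(sim, "tau"), tau)
    ref <- targeting_curve(t, tau = tau, lag = 0, plateau = C0 * g$S)
    expect_equal(sim$N, ref, tolerance = 1e-6)
  }
})

test_that("particle-mode flux agrees with the ODE within 3 SE", {
  g <- geometry_params(R = 1, D = 0.035)
  t <- seq(1, 10, 1)
  ode <- simulate_flux(6, g, t = t)
  set.seed(2)
  reps <- replicate(200, simulate_flux(6, g, t = t, mode = "particle",
                                       n_particles = 500)$N)
  mn <- rowMeans(reps)
  se <- apply(reps, 1, sd) / sqrt(ncol(reps))
  expect_true(all(abs(mn - ode$N) <= 3 * se))
})

test_that("zero connections give zero flux", {
  g <- geometry_params(R = 1, D = 0.035)
  expect_equal(simulate_flux(0, g, t = 0:10)$N, rep(0, 11))
  expect_equal(simulate_flux(0, g, t = 0:10, mode = "particle", seed = 1)$N,
               rep(0, 11))
})
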