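# Synthetic-data generators: defining closed forms at zero noise, planted
# ground truth, and bit-reproducibility under a fixed seed.

test_that("seeded generator runs are bit-reproducible", {
  a <- sim_field(seed = 99, render = TRUE, n_ld = 8, n_foci = 10)
  b <- sim_field(seed = 99, render = TRUE, n_ld = 8, n_foci = 10)
  expect_identical(a$image, b$image)
  expect_identical(as.data.frame(a$lds), as.data.frame(b$lds))
  expect_identical(as.data.frame(a$foci), as.data.frame(b$foci))
  expect_identical(sim_timecourse(seed = 3, noise_sd = 0.1)$intensity,
                   sim_timecourse(seed = 3, noise_sd = 0.1)$intensity)
  expect_identical(sim_drop_series(seed = 4, noise_frac = 0.02)$volume_ul,
                   sim_drop_series(seed = 4, noise_frac = 0.02)$volume_ul)
  expect_identical(sim_size_population("bimodal", n = 50, seed = 5),
                   sim_size_population("bimodal", n = 50, seed = 5))
})

test_that("planted colocalization flags follow the enrichment parameter", {
  # no LDs: overlap is impossible regardless of the requested enrichment
  f0 <- sim_field(n_ld = 0, n_foci = 10, enrichment = 1, seed = 1, render = FALSE)
  expect_equal(sum(f0$foci$colocalized), 0)
  # full enrichment: every focus is planted on an LD, and the analysis-side
  # overlap rule agrees with the planted flag
  f1 <- sim_field(n_ld = 5, n_foci = 5, enrichment = 1, seed = 2, render = FALSE)
  expect_true(all(f1$foci$colocalized))
  d <- signed_nn_distances(f1$foci, f1$lds)
  expect_true(all(d$signed_distance <= 0))
})

test_that("uniform foci hit LDs at the analytic dilated-area rate", {
  # Monte-Carlo placement over many fields vs the closed-form s, 3 binomial SE
  set.seed(11)
  n_fields <- 300
  hits <- 0; total <- 0; s_sum <- 0
  for (i in seq_len(n_fields)) {
    f <- sim_field(n_ld = 15, n_foci = 50, enrichment = 0, render = FALSE)
    d <- signed_nn_distances(f$foci, f$lds)
    hits <- hits + sum(d$colocalized)
    total <- total + nrow(f$foci)
    s_sum <- s_sum + as.numeric(dilated_area_fraction(f$lds, r_a = 0.1))
  }
  s_bar <- s_sum / n_fields
  se <- sqrt(s_bar * (1 - s_bar) / total)
  expect_lt(abs(hits / total - s_bar), 3 * se)
})

test_that("overcrowded fields fail with an error naming the constraint", {
  expect_error(
    sim_field(field_width = 4, field_height = 4, n_ld = 40,
              ld_radius_law = list(law = "fixed", radius = 0.8),
              seed = 1, render = FALSE, max_tries = 50),
    "overcrowded"
  )
})

test_that("targeting curves satisfy their closed form at zero noise", {
  tc <- sim_timecourse(t = seq(0, 40, 0.5), tau = 3.6, lag = 5, plateau = 2,
                       noise_sd = 0)
  expect_equal(tc$intensity[tc$t <= 5], rep(0, sum(tc$t <= 5)))
  expect_equal(tc$intensity, 2 * (1 - exp(-pmax(tc$t - 5, 0) / 3.6)))
  # saturation limit
  far <- sim_timecourse(t = c(0, 1e6), tau = 3.6, lag = 0, plateau = 2)
  expect_equal(far$intensity[2], 2)
  expect_error(sim_timecourse(t = c(0, 2, 1)), "increasing")
  expect_error(sim_timecourse(tau = -1), "tau")
})

test_that("FRAP curves start at 1 - beta and recover fully", {
  fr <- sim_frap_curve(t = c(0, 1, 1e9), D = 0.035, w = 2, beta = 0.8)
  expect_equal(fr$intensity[1], 0.2)
  expect_equal(fr$intensity[3], 1, tolerance = 1e-3)
  expect_true(all(diff(fr$intensity) > 0))
})

test_that("drop series are self-consistent and mass grows with gamma", {
  s <- sim_drop_series(gamma = 30, d = 250, delta_rho = 85, n_drops = 5,
                       noise_frac = 0)
  expect_equal(surface_tension(s)$gamma, 30, tolerance = 1e-8)
  s2 <- sim_drop_series(gamma = 60, d = 250, delta_rho = 85, n_drops = 5,
                        noise_frac = 0)
  expect_gt(mean(s2$volume_ul), mean(s$volume_ul))  # m = v * delta_rho
  expect_equal(attr(s, "d_um"), 250)
})

test_that("size population laws have the configured structure", {
  d <- sim_size_population("monodisperse", n = 1000, seed = 1)
  expect_lt(abs(mean(d) - 1.3) / 1.3, 0.02)
  expect_error(sim_size_population("weird", n = 10), "mode")
  g <- sim_size_population("giant", n = 1000, seed = 2)
  expect_gt(mean(g), mean(d))  # heavy right tail sits above the monodisperse mean
})

test_that("fields round-trip through TIFF and particle CSV", {
  f <- sim_field(n_ld = 4, n_foci = 6, seed = 7, field_width = 10,
                 field_height = 8, noise_sd = 0)
  tif <- withr::local_tempfile(fileext = ".tif")
  write_field_tiff(f, tif)
  img <- read_field_tiff(tif)
  expect_equal(dim(img), dim(f$image))
  expect_equal(img[, , "ld"], f$image[, , "ld"], tolerance = 1e-4)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_particles_csv(f$lds, csv)
  back <- read_particles_csv(csv)
  expect_equal(back$x_um, f$lds$x_um, tolerance = 1e-8)
  expect_equal(attr(back, "area_f"), attr(f$lds, "area_f"))
})
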