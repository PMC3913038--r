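# Segmentation: threshold-binarize-label against planted ground truth.

test_that("well-separated disks are recovered with matching geometry", {
  f <- sim_field(n_ld = 12, n_foci = 0, seed = 3, field_width = 30,
                 field_height = 30, pixel_size = 0.1, noise_sd = 10)
  ps <- segment_particles(f$image[, , "ld"], pixel_size = 0.1, channel = "ld")
  expect_equal(nrow(ps), 12)  # recall and precision both 1
  truth <- f$lds[order(f$lds$x_um), ]
  got <- ps[order(ps$x_um), ]
  expect_equal(got$x_um, truth$x_um, tolerance = 0.05)
  expect_equal(got$y_um, truth$y_um, tolerance = 0.05)
  # equivalent radii within one pixel of the planted radii
  expect_true(all(abs(got$radius_um - truth$radius_um) < 0.1))
  expect_equal(attr(ps, "area_f"), 900)
})

test_that("segmentation is deterministic", {
  f <- sim_field(n_ld = 6, n_foci = 0, seed = 8, noise_sd = 15)
  a <- segment_particles(f$image[, , "ld"], 0.1)
  b <- segment_particles(f$image[, , "ld"], 0.1)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("degenerate images yield empty particle sets, bad input errors", {
  flat <- matrix(0, 50, 50)
  ps <- segment_particles(flat, 0.1)
  expect_s3_class(ps, "particle_set")
  expect_equal(nrow(ps), 0)
  expect_error(segment_particles(array(0, c(5, 5, 2)), 0.1), "2-D")
  expect_error(segment_particles(matrix(0, 5, 5), -1), "pixel_size")
})

test_that("the minimum-area filter removes sub-threshold specks", {
  img <- matrix(0, 60, 60)
  img[30:31, 30] <- 1        # 3-px L-shaped speck
  img[30, 31] <- 1
  expect_equal(nrow(segment_particles(img, 0.1, threshold = 0.5,
                                      min_area_px = 5)), 0)
  expect_equal(nrow(segment_particles(img, 0.1, threshold = 0.5,
                                      min_area_px = 3)), 1)
})

test_that("foci channel segments and feeds the colocalization stage", {
  f <- sim_field(n_ld = 8, n_foci = 12, enrichment = 1, seed = 9,
                 field_width = 30, field_height = 30, noise_sd = 5)
  lds <- segment_particles(f$image[, , "ld"], 0.1, "ld")
  foci <- segment_particles(f$image[, , "foci"], 0.1, "foci", min_area_px = 2)
  expect_gt(nrow(foci), 0)
  res <- coloc_field(foci, lds)
  expect_equal(res$verdict, "enriched")
})
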