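# Colocalization statistics: signed distances, dilated-area fraction,
# binomial null, per-field verdicts and the condition-level aggregate.

make_ps <- function(x, y, r, w = 20, h = 20, channel = "p") {
  particle_set(data.frame(x_um = x, y_um = y, radius_um = r), w, h,
               pixel_size = 0.1, channel = channel)
}

test_that("signed distances match hand values and the brute-force oracle", {
  lds <- make_ps(5, 5, 0.5, channel = "ld")
  # focus at the LD centre: -(r_ld + r_a)
  expect_equal(signed_nn_distances(make_ps(5, 5, 0.1), lds)$signed_distance, -0.6)
  # separation 1.0, radii sum 0.6 -> +0.4
  expect_equal(signed_nn_distances(make_ps(6, 5, 0.1), lds)$signed_distance, 0.4)
  # several LDs at varying ranges: equals exhaustive pair enumeration
  set.seed(21)
  lds3 <- make_ps(runif(3, 2, 18), runif(3, 2, 18), runif(3, 0.3, 1), channel = "ld")
  foci <- make_ps(runif(25, 0, 20), runif(25, 0, 20), rep(0.12, 25))
  got <- signed_nn_distances(foci, lds3)
  expect_equal(got$signed_distance, brute_force_signed_nn(foci, lds3))
  expect_equal(got$colocalized, got$signed_distance <= 0)
  # no LDs: +Inf sentinel
  empty <- make_ps(numeric(0), numeric(0), numeric(0), channel = "ld")
  expect_true(all(is.infinite(signed_nn_distances(foci, empty)$signed_distance)))
})

test_that("mismatched pixel sizes are rejected", {
  a <- particle_set(data.frame(x_um = 1, y_um = 1, radius_um = 0.1), 10, 10,
                    pixel_size = 0.1)
  b <- particle_set(data.frame(x_um = 1, y_um = 1, radius_um = 0.5), 10, 10,
                    pixel_size = 0.2)
  expect_error(signed_nn_distances(a, b), "pixel size")
})

test_that("dilated area fraction is a clipped union, validated by Monte Carlo", {
  # single disk: pi r^2 / area_f
  one <- make_ps(10, 10, 1, channel = "ld")
  expect_equal(as.numeric(dilated_area_fraction(one, 0, resolution = 0.01)),
               pi / 400, tolerance = 1e-3)
  # coincident disks: union, not sum
  two <- make_ps(c(10, 10), c(10, 10), c(1, 1), channel = "ld")
  s2 <- dilated_area_fraction(two, 0, resolution = 0.01)
  expect_equal(as.numeric(s2), pi / 400, tolerance = 1e-3)
  expect_equal(attr(s2, "s_sum"), 2 * pi / 400)  # the naive sum is logged
  # zero LDs
  expect_equal(as.numeric(dilated_area_fraction(
    make_ps(numeric(0), numeric(0), numeric(0)), 0.2,
    field_width = 20, field_height = 20)), 0)
  # many random LDs vs uniform point sampling, 3 SE
  set.seed(31)
  lds <- make_ps(runif(50, 1, 19), runif(50, 1, 19), runif(50, 0.2, 0.8),
                 channel = "ld")
  s <- as.numeric(dilated_area_fraction(lds, r_a = 0.15, resolution = 0.02))
  n_pts <- 2e5
  mc <- mc_union_fraction(lds, 0.15, 20, 20, n_pts)
  expect_lt(abs(s - mc), 3 * sqrt(s * (1 - s) / n_pts))
  expect_true(s >= 0 && s <= 1)
})

test_that("binomial null matches direct evaluation and placement enumeration", {
  null <- binomial_null(4, 0.25)
  expect_equal(null$pmf$prob[null$pmf$n == 1], 4 * 0.25 * 0.75^3)
  expect_equal(null$n_s, 1)
  # enumeration over all 2^6 placements of 6 foci
  expect_equal(binomial_null(6, 0.3)$pmf$prob, enumerate_binomial_pmf(6, 0.3))
  # degenerate probabilities
  expect_equal(binomial_null(7, 0)$n_s, 0)
  expect_equal(binomial_null(7, 0)$pmf$prob[1], 1)
  expect_equal(binomial_null(7, 1)$n_s, 7)
  # pmf sums to one even for large fields
  for (na in c(10, 500, 10000)) {
    expect_equal(sum(binomial_null(na, 0.137)$pmf$prob), 1, tolerance = 1e-12)
  }
})

test_that("verdicts use exact binomial tails", {
  expect_equal(coloc_verdict(30, 100, 0.1)$verdict, "enriched")
  expect_lt(coloc_verdict(30, 100, 0.1)$tail_p,
            sum(dbinom(30:100, 100, 0.1)) + 1e-15)
  # at the mode of the null nothing is significant
  ns <- binomial_null(60, 0.2)$n_s
  expect_equal(coloc_verdict(ns, 60, 0.2)$verdict, "random-consistent")
  # zero observed out of 50 at s = 0.3: lower tail 0.7^50
  v <- coloc_verdict(0, 50, 0.3)
  expect_equal(v$verdict, "excluded")
  expect_equal(v$tail_p, 0.7^50)
  expect_error(coloc_verdict(5, 10, 0.2, alpha = 1.2), "alpha")
  expect_error(coloc_verdict(11, 10, 0.2), "exceed")
})

test_that("verdict is monotone in n_exp at fixed (n_a, s)", {
  ranks <- c("excluded" = 1, "random-consistent" = 2, "enriched" = 3)
  v <- vapply(0:40, function(n) coloc_verdict(n, 40, 0.25)$verdict, character(1))
  expect_true(all(diff(ranks[v]) >= 0))
  expect_setequal(unique(v), names(ranks))  # all three verdicts occur
})

test_that("aggregate_fields pools fields with a paired t test", {
  set.seed(41)
  res <- lapply(1:30, function(i) {
    f <- sim_field(n_ld = 15, n_foci = 50, enrichment = 0.6, render = FALSE)
    coloc_field(f$foci, f$lds)
  })
  agg <- aggregate_fields(res)
  expect_lt(agg$p_value, 0.01)
  expect_equal(agg$verdict, "enriched")
  expect_equal(agg$n_fields, 30)
  # degenerate variance is an explicit error
  same <- list(coloc_verdict(2, 10, 0.2), coloc_verdict(2, 10, 0.2))
  expect_error(aggregate_fields(same), "degenerate")
  expect_error(aggregate_fields(list(coloc_verdict(1, 5, 0.1))), ">= 2")
})

test_that("uniform fields aggregate to a random-consistent pooled verdict", {
  # the null mode n_s sits up to ~0.5/n_a below the null mean, so fields must
  # carry enough expected colocalization (n_a * s >> 1) for the paired t test
  # to be calibrated; use dense fields with many foci
  set.seed(43)
  ok <- vapply(1:10, function(rep) {
    res <- lapply(1:15, function(i) {
      f <- sim_field(n_ld = 25, n_foci = 200, enrichment = 0, render = FALSE)
      coloc_field(f$foci, f$lds)
    })
    aggregate_fields(res, alpha = 0.01)$verdict == "random-consistent"
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})
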