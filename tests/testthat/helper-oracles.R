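# Independent oracles used across tests. These deliberately share no code
# with the implementation paths they check.

# Brute-force signed nearest-neighbour distance: explicit loop over all pairs.
brute_force_signed_nn <- function(foci, lds) {
  vapply(seq_len(nrow(foci)), function(i) {
    best <- Inf
    for (j in seq_len(nrow(lds))) {
      d <- sqrt((foci$x_um[i] - lds$x_um[j])^2 + (foci$y_um[i] - lds$y_um[j])^2) -
        (foci$radius_um[i] + lds$radius_um[j])
      if (d < best) best <- d
    }
    best
  }, numeric(1))
}

# Monte-Carlo union area of dilated disks: uniform random points in the field.
mc_union_fraction <- function(lds, r_a, field_width, field_height, n_points) {
  px <- runif(n_points, 0, field_width)
  py <- runif(n_points, 0, field_height)
  inside <- rep(FALSE, n_points)
  for (j in seq_len(nrow(lds))) {
    inside <- inside |
      ((px - lds$x_um[j])^2 + (py - lds$y_um[j])^2 <= (lds$radius_um[j] + r_a)^2)
  }
  mean(inside)
}

# Binomial pmf by enumerating all 2^n placement outcomes of n independent foci.
enumerate_binomial_pmf <- function(n, s) {
  counts <- numeric(n + 1)
  for (k in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(k))[seq_len(n)]
    m <- sum(bits)
    counts[m + 1] <- counts[m + 1] + s^m * (1 - s)^(n - m)
  }
  counts
}
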