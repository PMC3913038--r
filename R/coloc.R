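# Object-based colocalization of protein foci with LDs under a binomial
# random-placement null.
#
# If foci fall uniformly over the field, the chance that one focus overlaps
# some LD equals the area fraction s of the field covered by the LDs after
# dilating each by the focus radius. The number of colocalized foci out of nA
# is then Binomial(nA, s); the observed count n_exp is compared with this
# exact null.

#' Signed nearest-neighbour distances between foci and LDs
#'
#' For each focus, the minimum over LDs of the centre-to-centre distance minus
#' the sum of the radii (`r_ld + r_focus`). Negative or zero distances mean
#' the focus overlaps (touches) an LD; a focus is called colocalized when its
#' signed distance is `<= 0`.
#'
#' @param foci,lds [particle_set()]s in the same coordinate frame (um).
#' @return A tibble with one row per focus: `x_um`, `y_um`, `radius_um`,
#'   `signed_distance` (um; `Inf` when there are no LDs), `nearest_ld` (row
#'   index into `lds`, `NA` when empty), `colocalized` (`signed_distance <= 0`).
#' @export
#' @examples
#' lds <- particle_set(data.frame(x_um = 5, y_um = 5, radius_um = 0.5),
#'                     10, 10, channel = "ld")
#' foci <- particle_set(data.frame(x_um = 5, y_um = 5, radius_um = 0.1),
#'                      10, 10, channel = "foci")
#' signed_nn_distances(foci, lds)$signed_distance  # -0.6
signed_nn_distances <- function(foci, lds) {
  pf <- attr(foci, "pixel_size"); pl <- attr(lds, "pixel_size")
  if (!is.null(pf) && !is.null(pl) && is.finite(pf) && is.finite(pl) &&
      abs(pf - pl) > 1e-9) {
    abort("`foci` and `lds` have different pixel sizes; they are not in the same frame.")
  }
  nf <- nrow(foci)
  if (nf == 0) {
    return(tibble(x_um = numeric(0), y_um = numeric(0), radius_um = numeric(0),
                  signed_distance = numeric(0), nearest_ld = integer(0),
                  colocalized = logical(0)))
  }
  if (nrow(lds) == 0) {
    return(tibble(x_um = foci$x_um, y_um = foci$y_um, radius_um = foci$radius_um,
                  signed_distance = Inf, nearest_ld = NA_integer_,
                  colocalized = FALSE))
  }
  dx <- outer(foci$x_um, lds$x_um, `-`)
  dy <- outer(foci$y_um, lds$y_um, `-`)
  d <- sqrt(dx^2 + dy^2) - outer(foci$radius_um, lds$radius_um, `+`)
  j <- max.col(-d, ties.method = "first")
  dmin <- d[cbind(seq_len(nf), j)]
  tibble(x_um = foci$x_um, y_um = foci$y_um, radius_um = foci$radius_um,
         signed_distance = dmin, nearest_ld = j, colocalized = dmin <= 0)
}

#' Dilated-LD area fraction of the field
#'
#' The probability `s` that a uniformly placed focus centre lands within
#' `r_ld + r_a` of some LD centre: each LD disk is dilated by the focus radius
#' `r_a`, and `s` is the area of the union of the dilated disks, clipped to
#' the field, divided by the field area. The union is computed on a raster of
#' spacing `resolution` with linear edge antialiasing, so coincident or
#' overlapping LDs are not double-counted and `s` is always a valid
#' probability. The naive sum `sum(pi * (r_ld + r_a)^2) / area_f`, which can
#' exceed 1 in crowded fields, is attached as attribute `s_sum` for
#' comparison.
#'
#' @param lds A [particle_set()] of LDs.
#' @param r_a Dilation radius (representative focus radius), um, `>= 0`.
#' @param field_width,field_height Field extent, um (attribute fallback).
#' @param resolution Raster spacing, um.
#' @return `s` in `[0, 1]`, with attribute `s_sum`.
#' @export
#' @examples
#' lds <- particle_set(data.frame(x_um = 5, y_um = 5, radius_um = 1), 10, 10)
#' dilated_area_fraction(lds, r_a = 0)  # ~ pi/100
dilated_area_fraction <- function(lds, r_a = 0,
                                  field_width = attr(lds, "field_width"),
                                  field_height = attr(lds, "field_height"),
                                  resolution = 0.05) {
  check_scalar(r_a, "r_a", nonneg = TRUE)
  check_scalar(field_width, "field_width", positive = TRUE)
  check_scalar(field_height, "field_height", positive = TRUE)
  check_scalar(resolution, "resolution", positive = TRUE)
  area_f <- field_width * field_height
  if (nrow(lds) == 0) {
    return(structure(0, s_sum = 0))
  }
  r <- lds$radius_um + r_a
  s_sum <- sum(pi * r^2) / area_f
  nx <- max(1L, round(field_width / resolution))
  ny <- max(1L, round(field_height / resolution))
  px <- field_width / nx  # use exact spacing so the raster tiles the field
  py <- field_height / ny
  cov <- matrix(0, nx, ny)
  for (i in seq_len(nrow(lds))) {
    i0 <- max(1L, floor((lds$x_um[i] - r[i]) / px)); i1 <- min(nx, ceiling((lds$x_um[i] + r[i]) / px) + 1L)
    j0 <- max(1L, floor((lds$y_um[i] - r[i]) / py)); j1 <- min(ny, ceiling((lds$y_um[i] + r[i]) / py) + 1L)
    if (i0 > nx || j0 > ny || i1 < 1L || j1 < 1L) next
    xc <- (seq.int(i0, i1) - 0.5) * px
    yc <- (seq.int(j0, j1) - 0.5) * py
    d <- sqrt(outer((xc - lds$x_um[i])^2, (yc - lds$y_um[i])^2, `+`))
    cc <- pmin(pmax(0.5 + (r[i] - d) / px, 0), 1)
    cov[i0:i1, j0:j1] <- pmax(cov[i0:i1, j0:j1], cc)
  }
  s <- sum(cov) * px * py / area_f
  structure(min(s, 1), s_sum = s_sum)
}

#' Exact binomial null for the colocalized count
#'
#' Probability mass function of the number of colocalized foci out of `n_a`
#' when each focus independently lands on the dilated LD area with probability
#' `s`, together with the most probable count `n_s` (the mode; ties broken
#' toward the smaller count).
#'
#' @param n_a Number of foci (>= 0).
#' @param s Single-focus colocalization probability in `[0, 1]`.
#' @return An object of class `coloc_null`: list with `pmf` (tibble `n`,
#'   `prob`), `n_s`, `n_a`, `s`.
#' @export
#' @examples
#' null <- binomial_null(4, 0.25)
#' null$pmf$prob[2]  # P(1) = 4 * 0.25 * 0.75^3
#' null$n_s
binomial_null <- function(n_a, s) {
  check_scalar(n_a, "n_a", nonneg = TRUE)
  check_scalar(s, "s", lower = 0, upper = 1)
  n_a <- as.integer(n_a)
  n <- 0:n_a
  prob <- dbinom(n, n_a, s)
  n_s <- n[which.max(prob)]  # which.max takes the first (smallest) tie
  structure(list(pmf = tibble(n = n, prob = prob), n_s = n_s, n_a = n_a, s = s),
            class = "coloc_null")
}

#' @export
print.coloc_null <- function(x, ...) {
  cat(sprintf("<coloc_null> Binomial(n_a = %d, s = %.4g); most probable count n_s = %d\n",
              x$n_a, x$s, x$n_s))
  invisible(x)
}

#' Enriched / excluded / random verdict for one field
#'
#' Compares the observed colocalized count `n_exp` with the exact binomial
#' null: the verdict is `"enriched"` when the upper tail `P(X >= n_exp)` is at
#' most `alpha`, `"excluded"` when the lower tail `P(X <= n_exp)` is at most
#' `alpha`, and `"random-consistent"` otherwise. `tail_p` reports the smaller
#' of the two tails.
#'
#' @param n_exp Observed number of colocalized foci (0..`n_a`).
#' @param n_a Total number of foci.
#' @param s Single-focus colocalization probability (see
#'   [dilated_area_fraction()]).
#' @param alpha Significance level in `(0, 1)`; 0.01 follows the significance
#'   level used for the condition-level comparisons.
#' @param distances Optional per-focus signed distance tibble (stored in the
#'   result).
#' @return An object of class `coloc_result`: list with `n_a`, `n_exp`, `s`,
#'   `n_s`, `tail_p`, `verdict`, `alpha`, `distances`.
#' @export
#' @examples
#' coloc_verdict(n_exp = 30, n_a = 100, s = 0.1)$verdict  # "enriched"
coloc_verdict <- function(n_exp, n_a, s, alpha = 0.01, distances = NULL) {
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  check_scalar(n_exp, "n_exp", nonneg = TRUE)
  check_scalar(n_a, "n_a", nonneg = TRUE)
  if (n_exp > n_a) abort("`n_exp` cannot exceed `n_a`.")
  null <- binomial_null(n_a, s)
  upper <- pbinom(n_exp - 1, n_a, s, lower.tail = FALSE)  # P(X >= n_exp)
  lower <- pbinom(n_exp, n_a, s)                          # P(X <= n_exp)
  verdict <- if (upper <= alpha) "enriched"
             else if (lower <= alpha) "excluded"
             else "random-consistent"
  structure(
    list(n_a = as.integer(n_a), n_exp = as.integer(n_exp), s = as.numeric(s),
         n_s = null$n_s, tail_p = min(upper, lower), upper_p = upper,
         lower_p = lower, verdict = verdict, alpha = alpha,
         distances = distances),
    class = "coloc_result"
  )
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf(
    "<coloc_result> n_exp = %d of n_a = %d (s = %.4g, null mode n_s = %d): %s (tail p = %.3g)\n",
    x$n_exp, x$n_a, x$s, x$n_s, x$verdict, x$tail_p
  ))
  invisible(x)
}

#' Colocalization verdict for one segmented field
#'
#' Convenience wrapper running the whole per-field analysis: signed
#' nearest-neighbour distances, observed colocalized count (signed distance
#' `<= 0`), dilated-area fraction `s` (dilation radius = mean focus radius
#' unless given), and the binomial verdict.
#'
#' @inheritParams signed_nn_distances
#' @inheritParams coloc_verdict
#' @param r_a Dilation radius; defaults to the mean focus radius.
#' @param resolution Raster spacing for the union area, um.
#' @return A `coloc_result` (see [coloc_verdict()]).
#' @export
coloc_field <- function(foci, lds, alpha = 0.01, r_a = NULL, resolution = 0.05) {
  d <- signed_nn_distances(foci, lds)
  r_a <- r_a %||% if (nrow(foci) > 0) mean(foci$radius_um) else 0
  s <- dilated_area_fraction(lds, r_a = r_a, resolution = resolution)
  coloc_verdict(n_exp = sum(d$colocalized), n_a = nrow(foci),
                s = as.numeric(s), alpha = alpha, distances = d)
}

#' Condition-level summary over fields
#'
#' Pairs, per field, the observed colocalized fraction `n_exp / n_a` with the
#' most probable null fraction `n_s / n_a` and tests their difference with a
#' two-sided paired t test across fields. The pooled verdict is `"enriched"`
#' (`"excluded"`) when the test is significant at `alpha` with a positive
#' (negative) mean difference, and `"random-consistent"` otherwise.
#'
#' @param results List of `coloc_result` objects (>= 2 fields with foci).
#' @param alpha Significance level for the pooled verdict.
#' @return An object of class `coloc_summary`: list with `fields` (tibble of
#'   per-field fractions and verdicts), `t`, `p_value`, `mean_diff`,
#'   `verdict`, `n_fields`.
#' @export
aggregate_fields <- function(results, alpha = 0.01) {
  if (!is.list(results) || length(results) < 2) {
    abort("`results` must be a list of >= 2 coloc_result objects.")
  }
  ok <- vapply(results, inherits, logical(1), what = "coloc_result")
  if (!all(ok)) abort("all elements of `results` must be coloc_result objects.")
  fields <- purrr::map_dfr(results, function(r) {
    tibble(n_a = r$n_a, n_exp = r$n_exp, s = r$s, n_s = r$n_s,
           obs_frac = if (r$n_a > 0) r$n_exp / r$n_a else NA_real_,
           null_frac = if (r$n_a > 0) r$n_s / r$n_a else NA_real_,
           verdict = r$verdict)
  })
  use <- !is.na(fields$obs_frac)
  if (!any(use)) abort("all fields are empty (n_a = 0); nothing to aggregate.")
  if (sum(use) < 2) abort("need >= 2 non-empty fields for a paired comparison.")
  diffs <- fields$obs_frac[use] - fields$null_frac[use]
  if (sd(diffs) == 0) {
    if (all(diffs == 0)) {
      abort("observed and null fractions are identical in every field; the paired t statistic is undefined (degenerate variance).")
    }
    # every field shows the exact same nonzero difference: the paired t
    # statistic diverges, which we report as its limit
    tstat <- sign(diffs[1]) * Inf
    pval <- 0
    mean_diff <- mean(diffs)
  } else {
    tt <- t.test(fields$obs_frac[use], fields$null_frac[use], paired = TRUE)
    tstat <- unname(tt$statistic)
    pval <- tt$p.value
    mean_diff <- unname(tt$estimate)
  }
  verdict <- if (pval < alpha) {
    if (mean_diff > 0) "enriched" else "excluded"
  } else "random-consistent"
  structure(
    list(fields = fields, t = tstat, p_value = pval,
         mean_diff = mean_diff, verdict = verdict,
         n_fields = sum(use), alpha = alpha),
    class = "coloc_summary"
  )
}

#' @export
print.coloc_summary <- function(x, ...) {
  cat(sprintf(
    "<coloc_summary> %d fields: mean(n_exp/n_a - n_s/n_a) = %.4g, t = %.3g, p = %.3g -> %s\n",
    x$n_fields, x$mean_diff, x$t, x$p_value, x$verdict
  ))
  invisible(x)
}
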