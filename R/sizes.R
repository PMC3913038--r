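# LD size-distribution summaries: kernel density estimates of diameter
# populations and mode counting, for comparing the bimodal control phenotype
# with monodisperse or giant-LD phenotypes.

#' Kernel density of an LD diameter population
#'
#' Gaussian kernel density estimate of LD diameters (um) with Silverman's
#' rule-of-thumb bandwidth by default, renormalized so the trapezoid integral
#' over the evaluation grid is exactly 1.
#'
#' @param diameters Numeric vector of diameters, um (all > 0, n >= 5).
#' @param bw Bandwidth rule or value, as in [stats::density()] (default
#'   `"nrd0"`, Silverman's rule).
#' @param n_grid Number of grid points.
#' @return A tibble `(diameter, density)` of class `ld_density` with
#'   attributes `bw` (um) and `n`.
#' @export
#' @examples
#' d <- sim_size_population("monodisperse", n = 200, seed = 1)
#' dens <- ld_density(d)
#' sum(diff(dens$diameter) * (head(dens$density, -1) + tail(dens$density, -1)) / 2)
ld_density <- function(diameters, bw = "nrd0", n_grid = 512) {
  diameters <- as.numeric(diameters)
  if (length(diameters) < 5) abort("need >= 5 diameters for a density estimate.")
  if (anyNA(diameters) || any(diameters <= 0)) abort("all diameters must be positive.")
  dens <- density(diameters, bw = bw, n = n_grid)
  integral <- sum(diff(dens$x) * (head(dens$y, -1) + tail(dens$y, -1)) / 2)
  structure(tibble(diameter = dens$x, density = dens$y / integral),
            bw = dens$bw, n = length(diameters), class = c("ld_density", "tbl_df",
                                                           "tbl", "data.frame"))
}

#' Summary statistics and modes of an LD size population
#'
#' Mean, median and the modes of the kernel density: local maxima whose
#' topographic prominence (height above the deepest saddle separating them
#' from higher terrain) is at least `prominence` times the global density
#' maximum. The floor suppresses both noise wiggles in the KDE tail and twin
#' micro-peaks riding on one true mode.
#'
#' @inheritParams ld_density
#' @param prominence Prominence floor for a mode, as a fraction of the global
#'   density maximum.
#' @return A list of class `ld_size_summary`: `n`, `mean`, `median`, `sd`,
#'   `modes` (tibble `diameter`, `density`), `n_modes`, `density` (the
#'   [ld_density()] tibble).
#' @export
#' @examples
#' d <- sim_size_population("bimodal", n = 500, seed = 1)
#' ld_size_summary(d)$n_modes
ld_size_summary <- function(diameters, bw = "nrd0", n_grid = 512,
                            prominence = 0.05) {
  check_scalar(prominence, "prominence", lower = 0, upper = 1)
  dens <- ld_density(diameters, bw = bw, n_grid = n_grid)
  y <- dens$density
  n <- length(y)
  left <- c(-Inf, y[-n]); right <- c(y[-1], -Inf)
  peaks <- which(y > left & y >= right)
  prom <- vapply(peaks, function(p) peak_prominence(y, p), numeric(1))
  keep <- prom >= prominence * max(y)
  modes <- tibble(diameter = dens$diameter[peaks[keep]], density = y[peaks[keep]])
  structure(
    list(n = length(diameters), mean = mean(diameters),
         median = median(diameters), sd = sd(diameters),
         modes = modes, n_modes = nrow(modes), density = dens),
    class = "ld_size_summary"
  )
}

# Topographic prominence of the peak y[p]: height above the higher of the
# two key saddles, where each side's saddle is the minimum between the peak
# and the nearest higher terrain; a side with no higher terrain contributes
# nothing, and a global maximum gets its full height.
peak_prominence <- function(y, p) {
  n <- length(y)
  saddle <- function(outward) {  # outward: indices from p towards one end
    higher <- outward[y[outward] > y[p]]
    if (length(higher) == 0) return(NA_real_)
    q <- higher[1]
    between <- outward[seq_len(which(outward == q) - 1)]
    if (length(between) == 0) y[p] else min(y[between])
  }
  lsad <- if (p > 1) saddle((p - 1):1) else NA_real_
  rsad <- if (p < n) saddle((p + 1):n) else NA_real_
  if (is.na(lsad) && is.na(rsad)) return(y[p])
  y[p] - max(lsad, rsad, na.rm = TRUE)
}

#' @export
print.ld_size_summary <- function(x, ...) {
  cat(sprintf(
    "<ld_size_summary> n = %d diameters: mean %.3g um, median %.3g um, %d mode(s) at %s um\n",
    x$n, x$mean, x$median, x$n_modes,
    paste(format(x$modes$diameter, digits = 3), collapse = ", ")
  ))
  invisible(x)
}
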