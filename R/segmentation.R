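# Threshold-then-binarize segmentation of a single fluorescence channel into
# a particle table. Thresholding, labelling and moments are delegated to
# EBImage; touching objects are not split (no watershed), since the binomial
# null only needs total dilated area.

#' Segment one channel into particles
#'
#' Applies a threshold (Otsu's method by default, for reproducibility across
#' fields), labels connected components, discards objects smaller than
#' `min_area_px`, and returns one particle per object with intensity-weighted
#' centroid (um) and equivalent radius `sqrt(area_um2 / pi)`.
#'
#' @param image A 2-D numeric matrix `[x, y]` (one channel), e.g. one slice of
#'   a [sim_field()] image or of [read_field_tiff()].
#' @param pixel_size Pixel size, um/px.
#' @param channel Channel label stored in the result.
#' @param threshold `"otsu"` or a fixed numeric threshold on the raw
#'   intensities.
#' @param min_area_px Minimum object area in pixels (smaller objects are
#'   treated as noise).
#' @return A [particle_set()] tibble (possibly 0 rows) with columns `x_um`,
#'   `y_um`, `radius_um`, `area_px`, `channel`.
#' @export
#' @examples
#' f <- sim_field(n_ld = 5, n_foci = 0, seed = 1)
#' segment_particles(f$image[, , "ld"], pixel_size = 0.1, channel = "ld")
segment_particles <- function(image, pixel_size, channel = "particle",
                              threshold = "otsu", min_area_px = 5) {
  if (!is.matrix(image) || !is.numeric(image)) {
    abort("`image` must be a 2-D numeric matrix (a single channel).")
  }
  check_scalar(pixel_size, "pixel_size", positive = TRUE)
  check_scalar(min_area_px, "min_area_px", nonneg = TRUE)
  nx <- nrow(image); ny <- ncol(image)
  rng <- range(image)
  empty <- particle_set(
    tibble(x_um = numeric(0), y_um = numeric(0), radius_um = numeric(0),
           area_px = numeric(0)),
    field_width = nx * pixel_size, field_height = ny * pixel_size,
    pixel_size = pixel_size, channel = channel
  )
  if (rng[1] == rng[2]) return(empty)  # flat image: nothing above threshold
  norm <- (image - rng[1]) / diff(rng)
  thr <- if (identical(threshold, "otsu")) {
    EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  } else {
    check_scalar(threshold, "threshold")
    (threshold - rng[1]) / diff(rng)
  }
  mask <- norm > thr
  if (!any(mask)) return(empty)
  labels <- EBImage::bwlabel(EBImage::Image(mask))
  shape <- EBImage::computeFeatures.shape(labels)
  mom <- EBImage::computeFeatures.moment(labels, ref = EBImage::Image(norm))
  keep <- shape[, "s.area"] >= min_area_px
  if (!any(keep)) return(empty)
  area_px <- unname(shape[keep, "s.area"])
  particle_set(
    tibble(
      x_um = unname(mom[keep, "m.cx"] - 0.5) * pixel_size,
      y_um = unname(mom[keep, "m.cy"] - 0.5) * pixel_size,
      radius_um = sqrt(area_px * pixel_size^2 / pi),
      area_px = as.numeric(area_px)
    ),
    field_width = nx * pixel_size, field_height = ny * pixel_size,
    pixel_size = pixel_size, channel = channel
  )
}

#' Write / read a particle table as CSV
#'
#' Plain-text interchange for particle sets: columns `x_um`, `y_um`,
#' `radius_um`, `area_px`, `channel` plus a header; the field geometry is
#' stored in commented key-value lines at the top of the file.
#'
#' @param ps A [particle_set()].
#' @param path File path.
#' @return `write_particles_csv()` returns `path` invisibly;
#'   `read_particles_csv()` returns a [particle_set()].
#' @export
write_particles_csv <- function(ps, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# field_width=%.10g", attr(ps, "field_width")), con)
  writeLines(sprintf("# field_height=%.10g", attr(ps, "field_height")), con)
  writeLines(sprintf("# pixel_size=%.10g", attr(ps, "pixel_size")), con)
  writeLines(sprintf("# channel=%s", attr(ps, "channel")), con)
  utils::write.csv(
    as.data.frame(ps)[, c("x_um", "y_um", "radius_um", "area_px", "channel")],
    con, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_particles_csv
#' @export
read_particles_csv <- function(path) {
  hdr <- readLines(path, n = 10)
  meta <- hdr[startsWith(hdr, "# ")]
  get <- function(key, as = as.numeric) {
    line <- meta[startsWith(meta, paste0("# ", key, "="))]
    if (length(line) == 0) return(NULL)
    as(sub(paste0("# ", key, "="), "", line[1]))
  }
  df <- utils::read.csv(path, comment.char = "#")
  particle_set(df,
               field_width = get("field_width"),
               field_height = get("field_height"),
               pixel_size = get("pixel_size") %||% NA_real_,
               channel = get("channel", as = identity) %||% "particle")
}
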