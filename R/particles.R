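#' Construct a particle set
#'
#' A particle set is a tibble of segmented (or planted) objects from one image
#' channel — one row per particle with centroid coordinates and equivalent
#' radius in micrometres — carrying the field geometry as attributes so that
#' downstream colocalization statistics know the field area.
#'
#' @param particles Data frame with at least columns `x_um`, `y_um`,
#'   `radius_um`. An `area_px` column is added as `NA` if absent.
#' @param field_width,field_height Field extent in micrometres.
#' @param pixel_size Pixel size in micrometres per pixel.
#' @param channel Channel label, e.g. `"ld"` or `"foci"`.
#'
#' @return A tibble of class `particle_set` with attributes `field_width`,
#'   `field_height`, `area_f` (field area, um^2), `pixel_size` and `channel`.
#' @export
#' @examples
#' lds <- particle_set(
#'   data.frame(x_um = c(2, 5), y_um = c(3, 7), radius_um = c(0.5, 0.8)),
#'   field_width = 10, field_height = 10, pixel_size = 0.1, channel = "ld"
#' )
#' attr(lds, "area_f")
particle_set <- function(particles, field_width, field_height,
                         pixel_size = NA_real_, channel = "particle") {
  check_scalar(field_width, "field_width", positive = TRUE)
  check_scalar(field_height, "field_height", positive = TRUE)
  particles <- as_tibble(particles)
  needed <- c("x_um", "y_um", "radius_um")
  missing <- setdiff(needed, names(particles))
  if (length(missing) > 0) {
    abort(paste0("`particles` lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (nrow(particles) > 0 && any(particles$radius_um <= 0)) {
    abort("all `radius_um` must be > 0.")
  }
  if (!"area_px" %in% names(particles)) particles$area_px <- NA_real_
  particles$channel <- channel
  structure(
    particles,
    field_width = field_width,
    field_height = field_height,
    area_f = field_width * field_height,
    pixel_size = pixel_size,
    channel = channel,
    class = c("particle_set", class(particles))
  )
}

field_area <- function(ps) {
  a <- attr(ps, "area_f")
  if (is.null(a)) abort("particle set lacks an `area_f` attribute; build it with particle_set().")
  a
}

#' @export
print.particle_set <- function(x, ...) {
  cat(sprintf(
    "<particle_set> %d particle(s), channel '%s', field %.3g x %.3g um\n",
    nrow(x), attr(x, "channel") %||% "?",
    attr(x, "field_width"), attr(x, "field_height")
  ))
  NextMethod()
}
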