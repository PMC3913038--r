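#' Simulate a two-channel fluorescence field of LDs and protein foci
#'
#' Generates one synthetic microscope field: disk-shaped lipid droplets in one
#' channel and punctate protein foci in a second channel, together with the
#' ground-truth particle table. Foci are either planted overlapping an LD
#' (with probability `enrichment`) or placed uniformly at random over the
#' field, which realizes the random-placement situation assumed by the
#' binomial colocalization null: the chance that a uniformly placed focus
#' centre lands within `r_ld + r_focus` of an LD centre equals the dilated-LD
#' area fraction of the field.
#'
#' A planted "colocalized" focus is centred uniformly within distance
#' `r_ld + focus_radius` of a randomly chosen LD centre, the same
#' centre-to-centre rule the analysis side uses to call an overlap, so
#' generation and analysis agree by construction. All particles are rejected
#' and resampled until they lie fully inside the field (no periodic boundary);
#' LDs are additionally kept from overlapping each other so each remains an
#' individually resolvable object.
#'
#' @param field_width,field_height Field extent, micrometres.
#' @param pixel_size Pixel size, micrometres per pixel (used when rendering).
#' @param n_ld Number of lipid droplets.
#' @param ld_radius_law LD radius law: either `list(law = "lognormal",
#'   meanlog, sdlog)` or `list(law = "fixed", radius)`. Radii in micrometres.
#' @param n_foci Number of protein foci.
#' @param focus_radius Focus radius, micrometres.
#' @param enrichment Probability in `[0, 1]` that a focus is planted
#'   overlapping an LD; `0` gives pure uniform placement.
#' @param background,peak Background and in-object intensity, arbitrary units.
#' @param noise_sd Standard deviation of additive zero-mean Gaussian noise.
#' @param seed Integer seed for reproducibility, or `NULL`.
#' @param render If `FALSE`, skip image synthesis and return only the ground
#'   truth (fast path for calibration studies over many fields).
#' @param max_tries Placement retries per particle before giving up with an
#'   error (the field is then too crowded for the requested configuration).
#'
#' @return A list of class `ld_field` with elements `image` (array
#'   `[x, y, channel]`, channels `ld` and `foci`; `NULL` when `render =
#'   FALSE`), `lds` and `foci` (ground-truth [particle_set()]s; `foci` has a
#'   logical `colocalized` column with the planted flag), and the generating
#'   parameters as attributes.
#' @export
#' @examples
#' f <- sim_field(n_ld = 5, n_foci = 10, enrichment = 1, seed = 1, render = FALSE)
#' all(f$foci$colocalized)
sim_field <- function(field_width = 25, field_height = 25, pixel_size = 0.1,
                      n_ld = 15,
                      ld_radius_law = list(law = "lognormal",
                                           meanlog = log(0.5), sdlog = 0.2),
                      n_foci = 50, focus_radius = 0.1, enrichment = 0,
                      background = 100, peak = 1000, noise_sd = 10,
                      seed = NULL, render = TRUE, max_tries = 2000) {
  check_scalar(field_width, "field_width", positive = TRUE)
  check_scalar(field_height, "field_height", positive = TRUE)
  check_scalar(pixel_size, "pixel_size", positive = TRUE)
  check_scalar(n_ld, "n_ld", nonneg = TRUE)
  check_scalar(n_foci, "n_foci", nonneg = TRUE)
  check_scalar(focus_radius, "focus_radius", positive = TRUE)
  check_scalar(enrichment, "enrichment", lower = 0, upper = 1)
  check_scalar(noise_sd, "noise_sd", nonneg = TRUE)

  with_seed(seed, {
    radii <- draw_radii(n_ld, ld_radius_law)
    if (any(2 * radii >= pmin(field_width, field_height))) {
      abort("an LD diameter exceeds the field; enlarge the field or shrink the radius law.")
    }
    lds_xy <- place_disks(radii, field_width, field_height, max_tries)
    lds <- particle_set(
      tibble(x_um = lds_xy$x, y_um = lds_xy$y, radius_um = radii),
      field_width, field_height, pixel_size, channel = "ld"
    )

    coloc <- if (n_foci > 0) runif(n_foci) < enrichment else logical(0)
    if (n_ld == 0) coloc[] <- FALSE  # no LD to overlap: flags are unattainable
    fx <- fy <- numeric(n_foci)
    for (i in seq_len(n_foci)) {
      if (coloc[i]) {
        p <- plant_colocalized(lds, focus_radius, field_width, field_height, max_tries)
      } else {
        p <- c(
          runif(1, focus_radius, field_width - focus_radius),
          runif(1, focus_radius, field_height - focus_radius)
        )
      }
      fx[i] <- p[1]; fy[i] <- p[2]
    }
    foci <- particle_set(
      tibble(x_um = fx, y_um = fy, radius_um = rep(focus_radius, n_foci),
             colocalized = coloc),
      field_width, field_height, pixel_size, channel = "foci"
    )

    image <- NULL
    if (render) {
      nx <- max(1L, round(field_width / pixel_size))
      ny <- max(1L, round(field_height / pixel_size))
      ld_img <- render_channel(lds$x_um, lds$y_um, lds$radius_um,
                               nx, ny, pixel_size, background, peak, noise_sd)
      fo_img <- render_channel(foci$x_um, foci$y_um, foci$radius_um,
                               nx, ny, pixel_size, background, peak, noise_sd)
      image <- array(c(ld_img, fo_img), dim = c(nx, ny, 2),
                     dimnames = list(NULL, NULL, c("ld", "foci")))
    }

    structure(
      list(image = image, lds = lds, foci = foci),
      field_width = field_width, field_height = field_height,
      pixel_size = pixel_size, enrichment = enrichment, seed = seed,
      class = "ld_field"
    )
  })
}

draw_radii <- function(n, law) {
  if (n == 0) return(numeric(0))
  if (!is.list(law) || is.null(law$law)) {
    abort("`ld_radius_law` must be a list with a `law` element ('lognormal' or 'fixed').")
  }
  switch(law$law,
    lognormal = rlnorm(n, meanlog = law$meanlog, sdlog = law$sdlog),
    fixed = rep(check_scalar(law$radius, "ld_radius_law$radius", positive = TRUE), n),
    abort(sprintf("unknown radius law '%s'.", law$law))
  )
}

# Rejection-sample non-overlapping disk centres fully inside the field.
place_disks <- function(radii, w, h, max_tries) {
  n <- length(radii)
  x <- y <- numeric(n)
  for (i in seq_len(n)) {
    r <- radii[i]
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      cx <- runif(1, r, w - r)
      cy <- runif(1, r, h - r)
      if (i == 1L ||
          all((cx - x[seq_len(i - 1)])^2 + (cy - y[seq_len(i - 1)])^2 >
              (r + radii[seq_len(i - 1)])^2)) {
        x[i] <- cx; y[i] <- cy; ok <- TRUE; break
      }
    }
    if (!ok) {
      abort(sprintf(
        paste0("could not place LD %d of %d without overlap after %d tries; ",
               "the field is overcrowded for n_ld and the radius law."),
        i, n, max_tries
      ))
    }
  }
  list(x = x, y = y)
}

# Centre a focus uniformly within (r_ld + r_focus) of a random LD centre,
# rejecting positions that stick out of the field.
plant_colocalized <- function(lds, r_focus, w, h, max_tries) {
  for (try in seq_len(max_tries)) {
    j <- sample.int(nrow(lds), 1)
    rmax <- lds$radius_um[j] + r_focus
    rad <- rmax * sqrt(runif(1))
    th <- runif(1, 0, 2 * pi)
    cx <- lds$x_um[j] + rad * cos(th)
    cy <- lds$y_um[j] + rad * sin(th)
    if (cx >= r_focus && cx <= w - r_focus && cy >= r_focus && cy <= h - r_focus) {
      return(c(cx, cy))
    }
  }
  abort(sprintf(
    "could not plant a colocalized focus inside the field after %d tries.",
    max_tries
  ))
}

# Anti-aliased disks: per-pixel coverage ramps linearly over one pixel at the
# rim; union of disks takes the max coverage per pixel.
render_channel <- function(x, y, r, nx, ny, px, background, peak, noise_sd) {
  img <- matrix(0, nx, ny)
  for (i in seq_along(x)) {
    i0 <- max(1L, floor((x[i] - r[i]) / px)); i1 <- min(nx, ceiling((x[i] + r[i]) / px) + 1L)
    j0 <- max(1L, floor((y[i] - r[i]) / px)); j1 <- min(ny, ceiling((y[i] + r[i]) / px) + 1L)
    if (i0 > i1 || j0 > j1) next
    xc <- (seq.int(i0, i1) - 0.5) * px
    yc <- (seq.int(j0, j1) - 0.5) * px
    d <- sqrt(outer((xc - x[i])^2, (yc - y[i])^2, `+`))
    cov <- pmin(pmax(0.5 + (r[i] - d) / px, 0), 1)
    img[i0:i1, j0:j1] <- pmax(img[i0:i1, j0:j1], cov)
  }
  out <- background + (peak - background) * img
  if (noise_sd > 0) out <- out + rnorm(length(out), sd = noise_sd)
  out
}

#' @export
print.ld_field <- function(x, ...) {
  cat(sprintf(
    "<ld_field> %.3g x %.3g um, %d LD(s), %d focus/foci (%d planted colocalized)%s\n",
    attr(x, "field_width"), attr(x, "field_height"),
    nrow(x$lds), nrow(x$foci), sum(x$foci$colocalized),
    if (is.null(x$image)) ", not rendered" else ""
  ))
  invisible(x)
}

#' Write / read a two-channel field as TIFF
#'
#' Channels are stored as separate directories of one multi-page 32-bit float
#' TIFF. Intensities are scaled by `full_scale` into `[0, 1]` on write and
#' scaled back on read.
#'
#' @param field An `ld_field` (must have been rendered).
#' @param path Output path.
#' @param full_scale Intensity corresponding to 1.0 in the file.
#' @return `write_field_tiff()` returns `path` invisibly; `read_field_tiff()`
#'   returns an array `[x, y, channel]`.
#' @export
write_field_tiff <- function(field, path, full_scale = 4095) {
  if (is.null(field$image)) abort("field was generated with render = FALSE; nothing to write.")
  pages <- lapply(seq_len(dim(field$image)[3]), function(k) {
    # tiff stores row-major [row = y]; transpose so x is the column axis
    pmin(pmax(t(field$image[, , k]) / full_scale, 0), 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_field_tiff
#' @export
read_field_tiff <- function(path, full_scale = 4095) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(
    unlist(lapply(pages, t)),
    dim = c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages)),
    dimnames = list(NULL, NULL, if (length(pages) == 2) c("ld", "foci") else NULL)
  )
  arr * full_scale
}
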