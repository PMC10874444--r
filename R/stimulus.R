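## Parametric stand-in for ray-traced PAL distortion fields.
##
## Real PAL distortions are computed by ray tracing through the lens
## surfaces; here a two-term parametric model reproduces their
## qualitative structure -- a cubic radial term whose sign follows the
## far power Sph (pincushion for plus lenses, barrel for minus lenses)
## and an Add-weighted lower-field term capturing the near-zone
## asymmetry.  The model gives synthetic ground-truth scales a physical
## anchor; its constants are configuration, not claims about any lens.

# Module constants.  With eccentricity r up to ~58 deg inside the
# aperture, r^3 reaches ~2e5 deg^3; the radial gain puts peak radial
# displacement for sph = 5 dpt at ~3.9 deg at the aperture edge -- a few
# degrees of visual angle, comparable to real PAL distortions.  The
# lower-field gain is kept small enough that severity remains strictly
# increasing in |sph| at fixed add over the stimulus grid (the radial
# term flips sign with sph and could otherwise cancel against the
# add-weighted term for minus lenses).
K_RADIAL <- 4e-6   # deg^-2 dpt^-1
K_LOWER <- 2e-4    # deg^-1 dpt^-1

#' Specify a lens condition
#'
#' A stimulus condition is a progressive addition lens described by its
#' far-zone spherical power and its near-zone addition power, or the
#' undistorted reference condition.
#'
#' @param sph Spherical (far) power in diopters; signed.
#' @param add Addition (near) power in diopters; non-negative.
#' @param is_reference Logical; `TRUE` only for the undistorted
#'   reference, which must have `sph = 0` and `add = 0`.
#' @return An object of class `lens_spec`: a list with elements `sph`,
#'   `add` and `is_reference`.
#' @examples
#' lens_spec(2.5, 1)
#' lens_spec(0, 0, is_reference = TRUE)
#' @export
lens_spec <- function(sph, add, is_reference = FALSE) {
  if (!is.numeric(sph) || length(sph) != 1L || !is.finite(sph)) {
    stopf("`sph` must be a single finite number")
  }
  if (!is.numeric(add) || length(add) != 1L || !is.finite(add) || add < 0) {
    stopf("`add` must be a single finite non-negative number")
  }
  if (is_reference && (sph != 0 || add != 0)) {
    stopf("the reference condition must have sph = 0 and add = 0")
  }
  structure(list(sph = sph, add = add, is_reference = is_reference),
            class = "lens_spec")
}

#' @export
format.lens_spec <- function(x, ...) {
  if (x$is_reference) "undistorted reference"
  else sprintf("lens Sph %+g dpt, Add %g dpt", x$sph, x$add)
}

#' @export
print.lens_spec <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Elliptical spectacle-frame aperture
#'
#' The simulated frame rim seen by the observer: an ellipse in visual
#' angle separating the distorted lens area from the undistorted
#' periphery.  Defaults correspond to a 116 x 80 degree inner ellipse
#' with a 2 degree rim.
#'
#' @param half_width,half_height Ellipse semi-axes in degrees.
#' @param thickness Rim thickness in degrees.
#' @return An object of class `frame_aperture`.
#' @export
frame_aperture <- function(half_width = 58, half_height = 40, thickness = 2) {
  if (half_width <= 0 || half_height <= 0) {
    stopf("aperture half-width and half-height must be positive")
  }
  structure(list(half_width = half_width, half_height = half_height,
                 thickness = thickness),
            class = "frame_aperture")
}

#' Generate a parametric distortion field for a lens
#'
#' Evaluates the two-term parametric distortion model on a regular
#' longitude/latitude lattice.  The displacement at visual-field
#' position `(lon, lat)` with eccentricity `r` is
#' `sign(sph) * k1 * |sph| * r^3` radially (pincushion for `sph > 0`,
#' barrel for `sph < 0`) plus `k2 * add * max(0, -lat) * r` radially
#' (the near-zone asymmetry: distortion grows in the lower field with
#' addition power).  The reference lens yields an identically zero
#' field.
#'
#' @param lens A [lens_spec()].
#' @param extent Numeric vector `c(lon_min, lon_max, lat_min, lat_max)`
#'   in degrees.
#' @param spacing Lattice spacing in degrees; must be positive.
#' @return An object of class `distortion_field`: list with vectors
#'   `lon`, `lat` (lattice axes) and matrices `dx`, `dy` (displacements
#'   in degrees, rows indexed by `lon`, columns by `lat`), plus the
#'   generating `lens`.
#' @examples
#' f <- make_distortion_field(lens_spec(2.5, 1))
#' max(sqrt(f$dx^2 + f$dy^2))
#' @export
make_distortion_field <- function(lens, extent = c(-60, 60, -45, 45),
                                  spacing = 1) {
  stopifnot(inherits(lens, "lens_spec"))
  if (!is.numeric(spacing) || spacing <= 0) {
    stopf("grid spacing must be positive")
  }
  if (length(extent) != 4L || extent[1] >= extent[2] || extent[3] >= extent[4]) {
    stopf("`extent` must be c(lon_min, lon_max, lat_min, lat_max) with min < max")
  }
  lon <- seq(extent[1], extent[2], by = spacing)
  lat <- seq(extent[3], extent[4], by = spacing)
  lon_g <- matrix(lon, nrow = length(lon), ncol = length(lat))
  lat_g <- matrix(lat, nrow = length(lon), ncol = length(lat), byrow = TRUE)
  r <- sqrt(lon_g^2 + lat_g^2)
  # radial unit vector; undefined at the origin where displacement is 0
  rhat_x <- ifelse(r > 0, lon_g / r, 0)
  rhat_y <- ifelse(r > 0, lat_g / r, 0)
  mag <- sign(lens$sph) * K_RADIAL * abs(lens$sph) * r^3 +
    K_LOWER * lens$add * pmax(0, -lat_g) * r
  structure(list(lon = lon, lat = lat,
                 dx = mag * rhat_x, dy = mag * rhat_y,
                 lens = lens),
            class = "distortion_field")
}

#' Scalar severity of a distortion field
#'
#' Root-mean-square displacement magnitude over lattice nodes inside the
#' aperture ellipse.  Used to anchor synthetic ground-truth scales and
#' to verify that catch-trial lenses are unambiguously the most
#' distorted stimulus.
#'
#' @param field A [make_distortion_field()] result.
#' @param aperture A [frame_aperture()].
#' @return RMS displacement in degrees (non-negative; zero iff the field
#'   vanishes inside the aperture).
#' @export
severity_index <- function(field, aperture = frame_aperture()) {
  stopifnot(inherits(field, "distortion_field"),
            inherits(aperture, "frame_aperture"))
  lon_g <- matrix(field$lon, nrow = length(field$lon), ncol = length(field$lat))
  lat_g <- matrix(field$lat, nrow = length(field$lon), ncol = length(field$lat),
                  byrow = TRUE)
  inside <- (lon_g / aperture$half_width)^2 +
    (lat_g / aperture$half_height)^2 <= 1
  if (!any(inside)) {
    stopf("no lattice node falls inside the aperture ellipse")
  }
  sqrt(mean((field$dx[inside]^2 + field$dy[inside]^2)))
}

#' Displace visual-field points through a distortion field
#'
#' Applies the field to arbitrary points by bilinear interpolation of
#' the lattice displacements.  The zero field acts as the identity.
#'
#' @param field A [make_distortion_field()] result.
#' @param points Two-column matrix or data frame of `(lon, lat)` in
#'   degrees; all points must lie within the lattice extent.
#' @return Matrix of displaced `(lon, lat)` coordinates.
#' @export
warp_points <- function(field, points) {
  stopifnot(inherits(field, "distortion_field"))
  pts <- as.matrix(points)
  if (ncol(pts) != 2L) stopf("`points` must have two columns (lon, lat)")
  lon <- field$lon
  lat <- field$lat
  if (any(pts[, 1] < lon[1] | pts[, 1] > lon[length(lon)] |
          pts[, 2] < lat[1] | pts[, 2] > lat[length(lat)])) {
    stopf("point outside the field's lattice extent")
  }
  interp <- function(z, p) {
    i <- pmin(findInterval(p[, 1], lon), length(lon) - 1L)
    j <- pmin(findInterval(p[, 2], lat), length(lat) - 1L)
    u <- (p[, 1] - lon[i]) / (lon[i + 1L] - lon[i])
    v <- (p[, 2] - lat[j]) / (lat[j + 1L] - lat[j])
    z[cbind(i, j)] * (1 - u) * (1 - v) +
      z[cbind(i + 1L, j)] * u * (1 - v) +
      z[cbind(i, j + 1L)] * (1 - u) * v +
      z[cbind(i + 1L, j + 1L)] * u * v
  }
  out <- pts
  out[, 1] <- pts[, 1] + interp(field$dx, pts)
  out[, 2] <- pts[, 2] + interp(field$dy, pts)
  out
}

#' Write or read a distortion field as long-format CSV
#'
#' Serializes a field as rows `(lon, lat, dx, dy)`, mirroring the
#' two-channel displacement-texture representation used for rendering.
#'
#' @param field A `distortion_field`.
#' @param path Output CSV path.
#' @return `write_field_csv()` returns `path` invisibly;
#'   `read_field_csv()` returns a `distortion_field` (without lens
#'   metadata).
#' @export
write_field_csv <- function(field, path) {
  stopifnot(inherits(field, "distortion_field"))
  grid <- expand.grid(lon = field$lon, lat = field$lat)
  grid$dx <- as.vector(field$dx)
  grid$dy <- as.vector(field$dy)
  write.csv(grid, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_field_csv
#' @export
read_field_csv <- function(path) {
  grid <- read.csv(path)
  need <- c("lon", "lat", "dx", "dy")
  if (!all(need %in% names(grid))) {
    stopf("field CSV must have columns %s", paste(need, collapse = ", "))
  }
  lon <- sort(unique(grid$lon))
  lat <- sort(unique(grid$lat))
  o <- order(grid$lat, grid$lon)
  structure(list(lon = lon, lat = lat,
                 dx = matrix(grid$dx[o], nrow = length(lon)),
                 dy = matrix(grid$dy[o], nrow = length(lon)),
                 lens = NULL),
            class = "distortion_field")
}
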