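#' Cylindrical PET scanner geometry
#'
#' Describes a cylindrical scanner as rings of crystals. Crystal centres lie
#' exactly on the cylinder of radius `ring_radius`; rings are spaced by
#' `crystal_axial_pitch` and centred on the axial origin. The scanner axis is
#' the z axis, oriented perpendicular to the animal platform, so that the
#' transaxial (x, y) plane is the horizontal plane the mouse moves in.
#'
#' @param ring_radius Ring radius in mm.
#' @param n_crystals_per_ring Number of crystals per ring (even, >= 8).
#' @param n_rings Number of rings.
#' @param crystal_axial_pitch Axial spacing between ring centres, mm.
#' @param name Preset or user label.
#' @return An object of class `scanner_geometry`.
#' @seealso [scanner_preset()], [crystal_positions()]
#' @export
scanner_geometry <- function(ring_radius, n_crystals_per_ring, n_rings,
                             crystal_axial_pitch, name = "custom") {
  stopifnot(ring_radius > 0, n_rings >= 1, crystal_axial_pitch > 0)
  if (n_crystals_per_ring < 8 || n_crystals_per_ring %% 2 != 0)
    stop("n_crystals_per_ring must be even and at least 8")
  structure(
    list(ring_radius = ring_radius,
         n_crystals_per_ring = as.integer(n_crystals_per_ring),
         n_rings = as.integer(n_rings),
         crystal_axial_pitch = crystal_axial_pitch,
         axial_fov = n_rings * crystal_axial_pitch,
         name = name),
    class = "scanner_geometry")
}

#' Scanner presets
#'
#' `"desk"` is the small default geometry used throughout the test-bench
#' simulations: 288 crystals on an 80 mm radius ring (the 100 x 90 mm
#' platform diagonal, plus the marker offsets on the head, then stays well
#' inside the transaxial field of view), 12 rings at 1.5 mm pitch — crystal
#' pitches close to real small-animal detectors, which sub-millimetre marker
#' tracking needs, but a short 18 mm axial extent to keep desk-scale
#' problems small. `"inveon-like"` mirrors a production small-animal scanner
#' with a 10 cm transaxial detector diameter and a 12.7 cm axial field of
#' view.
#'
#' @param name `"desk"` or `"inveon-like"`.
#' @return A `scanner_geometry`.
#' @export
scanner_preset <- function(name = c("desk", "inveon-like")) {
  name <- match.arg(name)
  switch(name,
    "desk" = scanner_geometry(80, 288L, 12L, 1.5, name = "desk"),
    "inveon-like" = scanner_geometry(50, 320L, 80L, 1.5875, name = "inveon-like"))
}

#' Crystal centre coordinates
#'
#' @param geom A `scanner_geometry`.
#' @return An (n_rings * n_crystals_per_ring) x 3 matrix of crystal centres in
#'   mm. Crystal `id` (1-based) maps to ring `(id - 1) %/% n_crystals_per_ring`
#'   and transaxial position `(id - 1) %% n_crystals_per_ring`.
#' @export
crystal_positions <- function(geom) {
  stopifnot(inherits(geom, "scanner_geometry"))
  nc <- geom$n_crystals_per_ring
  nr <- geom$n_rings
  phi <- 2 * pi * (seq_len(nc) - 1) / nc
  z <- (seq_len(nr) - 1 - (nr - 1) / 2) * geom$crystal_axial_pitch
  cbind(
    x = rep(geom$ring_radius * cos(phi), nr),
    y = rep(geom$ring_radius * sin(phi), nr),
    z = rep(z, each = nc))
}

#' Total number of crystals
#' @param geom A `scanner_geometry`.
#' @export
n_crystals <- function(geom) geom$n_crystals_per_ring * geom$n_rings

#' @export
print.scanner_geometry <- function(x, ...) {
  cat(sprintf(
    "<scanner_geometry '%s'> radius %.1f mm, %d crystals/ring x %d rings, axial FOV %.1f mm\n",
    x$name, x$ring_radius, x$n_crystals_per_ring, x$n_rings, x$axial_fov))
  invisible(x)
}

#' Regular voxel grid specification
#'
#' World coordinates are mm; the world position of the centre of voxel
#' (0,0,0) (0-based) is `origin + 0.5 * voxel_size`.
#'
#' @param shape Integer vector of 3 voxel counts.
#' @param voxel_size Voxel edge lengths in mm (length 1 or 3).
#' @param origin World coordinate (mm) of the corner of the first voxel;
#'   default centres the grid on the world origin.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(shape, voxel_size, origin = NULL) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 1))
  voxel_size <- rep_len(as.numeric(voxel_size), 3)
  stopifnot(all(voxel_size > 0))
  if (is.null(origin)) origin <- -shape * voxel_size / 2
  stopifnot(length(origin) == 3)
  structure(list(shape = shape, voxel_size = voxel_size,
                 origin = as.numeric(origin)),
            class = "grid_spec")
}

#' Grid presets
#'
#' `"desk"` is a 64 x 64 x 16 grid of 1 mm voxels centred on the scanner (the
#' head-phantom frame); `"desk-coarse"` covers the whole desk transaxial FOV
#' at 1.5 mm for short-frame tracking; `"inveon-like"` reproduces a
#' 128 x 128 x 159 matrix with 0.776 x 0.776 x 0.796 mm voxels.
#'
#' @param name Preset name.
#' @return A `grid_spec`.
#' @export
grid_preset <- function(name = c("desk", "desk-coarse", "inveon-like")) {
  name <- match.arg(name)
  switch(name,
    "desk" = grid_spec(c(64, 64, 16), 1),
    "desk-coarse" = grid_spec(c(108, 108, 12), 1.5),
    "inveon-like" = grid_spec(c(128, 128, 159), c(0.776, 0.776, 0.796)))
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d x %d voxels of %.3g x %.3g x %.3g mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

#' Voxel volume in cm^3
#' @param grid A `grid_spec`.
#' @export
voxel_volume_cm3 <- function(grid) prod(grid$voxel_size) / 1000

#' Voxel centre coordinates
#'
#' @param grid A `grid_spec`.
#' @return An nvox x 3 matrix of voxel centres (mm) in R column-major order.
#' @export
voxel_centers <- function(grid) {
  s <- grid$shape; v <- grid$voxel_size; o <- grid$origin
  cx <- o[1] + (seq_len(s[1]) - 0.5) * v[1]
  cy <- o[2] + (seq_len(s[2]) - 0.5) * v[2]
  cz <- o[3] + (seq_len(s[3]) - 0.5) * v[3]
  cbind(x = rep(cx, times = s[2] * s[3]),
        y = rep(rep(cy, each = s[1]), times = s[3]),
        z = rep(cz, each = s[1] * s[2]))
}

same_grid <- function(a, b, tol = 1e-6) {
  all(a$shape == b$shape) &&
    all(abs(a$voxel_size - b$voxel_size) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}
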