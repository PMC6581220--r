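#' Voxelised activity or reconstruction image
#'
#' @param grid A [grid_spec()].
#' @param values 3-D numeric array (or vector of matching length) of voxel
#'   values; activity images are in kBq/cm^3, reconstructions are unitless.
#' @param activity Logical; if `TRUE` values must be nonnegative.
#' @return An object of class `voxel_image`.
#' @export
voxel_image <- function(grid, values, activity = FALSE) {
  stopifnot(inherits(grid, "grid_spec"))
  values <- array(as.numeric(values), dim = grid$shape)
  if (any(!is.finite(values))) stop("voxel values must be finite")
  if (activity && any(values < 0)) stop("activity images must be nonnegative")
  structure(list(grid = grid, values = values), class = "voxel_image")
}

#' @export
print.voxel_image <- function(x, ...) {
  cat(sprintf("<voxel_image> %s, range [%.4g, %.4g]\n",
              paste(x$grid$shape, collapse = " x "),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Linear attenuation coefficient map
#'
#' @param grid A [grid_spec()].
#' @param mu 3-D array of attenuation coefficients in cm^-1 (nonnegative).
#' @return An object of class `mu_map`.
#' @export
mu_map <- function(grid, mu) {
  stopifnot(inherits(grid, "grid_spec"))
  mu <- array(as.numeric(mu), dim = grid$shape)
  if (any(!is.finite(mu)) || any(mu < 0)) stop("mu must be finite and >= 0")
  structure(list(grid = grid, mu = mu), class = "mu_map")
}

#' Soft-tissue linear attenuation coefficient, cm^-1
#'
#' The constant value assumed for the whole mouse body when attenuation is
#' derived from the body activity outline.
#' @export
MU_SOFT_TISSUE <- 0.097

#' Integer-labelled brain atlas
#'
#' Labels partition the grid; label 0 is background and the named regions are
#' required to be nonempty.
#'
#' @param grid A [grid_spec()].
#' @param labels 3-D integer array of region labels.
#' @param region_names Named integer vector mapping region name -> label;
#'   must not include background (0).
#' @return An object of class `brain_atlas`.
#' @export
brain_atlas <- function(grid, labels, region_names) {
  stopifnot(inherits(grid, "grid_spec"))
  labels <- array(as.integer(labels), dim = grid$shape)
  stopifnot(is.numeric(region_names), !is.null(names(region_names)))
  region_names <- vapply(region_names, as.integer, integer(1))
  if (any(region_names == 0L)) stop("label 0 is reserved for background")
  for (nm in names(region_names))
    if (!any(labels == region_names[[nm]]))
      stop("atlas region '", nm, "' is empty")
  structure(list(grid = grid, labels = labels, region_names = region_names),
            class = "brain_atlas")
}

#' The five quantified brain regions
#' @export
BRAIN_REGIONS <- c("cortex", "caudate_putamen", "thalamus", "hippocampus",
                   "cerebellum")
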