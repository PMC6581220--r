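#' Fiducial marker model
#'
#' Four ~1-mm radioactive point sources glued to the head define the rigid
#' reference the tracker matches against. The default layout mimics the
#' in-vivo arrangement: one marker under each ear, one on the nasal bridge
#' and one raised on a lightweight spacer. The tetrahedron must be
#' non-coplanar (otherwise the pose is ambiguous) and its six pairwise
#' distances must be pairwise distinct by at least `distance_margin` so the
#' distance-based matching has a unique ordering.
#'
#' @param points 4 x 3 matrix of marker coordinates (mm) in the head frame.
#' @param activities Marker activities in kBq (default mid-range of the
#'   296-370 kBq sources used in practice).
#' @param diameter Marker diameter in mm.
#' @param activity_range Allowed activity range, kBq.
#' @param distance_margin Minimum separation (mm) between any two of the six
#'   pairwise distances.
#' @return An object of class `marker_model`.
#' @export
marker_model <- function(points, activities = c(330, 310, 350, 300),
                         diameter = 1,
                         activity_range = c(296, 370),
                         distance_margin = 0.5) {
  points <- as.matrix(points)
  if (nrow(points) != 4 || ncol(points) != 3)
    stop("marker model requires exactly 4 points in 3-D")
  sv <- svd(scale(points, scale = FALSE))$d
  if (sv[3] < 0.5)
    stop("marker points are (nearly) coplanar; pose estimation would be ambiguous")
  if (length(activities) != 4 || any(activities < activity_range[1]) ||
      any(activities > activity_range[2]))
    stop("marker activities must be 4 values within [",
         activity_range[1], ", ", activity_range[2], "] kBq")
  d <- pair_distances(points)
  if (min(diff(sort(d))) < distance_margin)
    stop("marker pairwise distances are not distinct by ", distance_margin,
         " mm; matching would be ambiguous")
  structure(list(points = unname(points), activities = as.numeric(activities),
                 diameter = diameter, pair_dist = d),
            class = "marker_model")
}

# The six unordered pairwise distances in fixed order
# (1,2) (1,3) (1,4) (2,3) (2,4) (3,4).
pair_distances <- function(points) {
  p <- utils::combn(4, 2)
  unname(sqrt(colSums((t(points[p[1, ], ]) - t(points[p[2, ], ]))^2)))
}

#' Default mouse-head marker layout
#'
#' @inheritParams marker_model
#' @return A `marker_model`.
#' @export
default_marker_model <- function(activities = c(330, 310, 350, 300)) {
  marker_model(rbind(
    ear_left  = c(-6.5, -0.1, -2.8),
    ear_right = c( 7.0, -4.8, -4.7),
    nasal     = c(-0.1, 10.2,  0.1),
    spacer    = c(-2.8,  1.3,  6.1)),
    activities = activities)
}

#' @export
print.marker_model <- function(x, ...) {
  cat("<marker_model> 4 points, pairwise distances (mm):",
      paste(sprintf("%.2f", sort(x$pair_dist)), collapse = ", "), "\n")
  invisible(x)
}

#' Default regional activity concentrations, kBq/cm^3
#'
#' The relative levels follow the regional FDG uptake pattern of the mouse
#' brain (caudate putamen and thalamus hottest, cortex and cerebellum lower).
#' @export
default_region_activities <- function() {
  c(cortex = 750, caudate_putamen = 925, thalamus = 1050,
    hippocampus = 870, cerebellum = 840)
}

#' Digital mouse-head phantom
#'
#' Builds a rigid digital phantom in the head reference frame: an ellipsoidal
#' body of uniform background activity enclosing an ellipsoidal brain that is
#' partitioned into the five quantified regions (cortex, caudate putamen,
#' thalamus, hippocampus, cerebellum). Activity is constant within each
#' region. The attenuation map is the soft-tissue constant 0.097 cm^-1 inside
#' the body and 0 outside.
#'
#' @param grid A [grid_spec()] (head frame, mm).
#' @param region_activities Named vector of activity concentrations
#'   (kBq/cm^3) for the five brain regions.
#' @param body List with `center` and `semiaxes` (mm) of the body ellipsoid.
#' @param body_activity Background (body) activity concentration, kBq/cm^3.
#' @return List with `activity` ([voxel_image()]), `mumap` ([mu_map()]) and
#'   `atlas` ([brain_atlas()]).
#' @export
make_head_phantom <- function(grid = grid_preset("desk"),
                              region_activities = default_region_activities(),
                              body = list(center = c(0, -8, 0),
                                          semiaxes = c(26, 20, 6.5)),
                              body_activity = 400) {
  if (any(region_activities < 0) || body_activity < 0)
    stop("region activities must be nonnegative")
  missing_r <- setdiff(BRAIN_REGIONS, names(region_activities))
  if (length(missing_r))
    stop("missing region activities: ", paste(missing_r, collapse = ", "))

  ctr <- voxel_centers(grid)
  x <- ctr[, 1]; y <- ctr[, 2]; z <- ctr[, 3]

  in_ellipsoid <- function(c0, s)
    ((x - c0[1]) / s[1])^2 + ((y - c0[2]) / s[2])^2 + ((z - c0[3]) / s[3])^2 <= 1

  body_mask <- in_ellipsoid(body$center, body$semiaxes)
  brain_semi <- c(6, 5, 4.5)
  brain <- in_ellipsoid(c(0, 0, 0), brain_semi)
  if (any(brain & !body_mask))
    stop("brain is not fully inside the body ellipsoid")

  r2 <- x^2 + y^2 + z^2
  lab <- integer(length(x))
  lab[body_mask] <- -1L                 # body background (label 0 in atlas,
                                        # but tracked for activity fill)
  codes <- stats::setNames(seq_along(BRAIN_REGIONS), BRAIN_REGIONS)
  cereb <- brain & y <= -3
  thal <- brain & r2 <= 1.8^2
  caud <- brain & !cereb & !thal &
    (((x - 2.8)^2 + (y - 2)^2 + (z - 0.5)^2 <= 1.4^2) |
     ((x + 2.8)^2 + (y - 2)^2 + (z - 0.5)^2 <= 1.4^2))
  hipp <- brain & !cereb & !thal & !caud & r2 >= 2.2^2 & r2 <= 3.4^2 & z >= 0
  cort <- brain & !cereb & !thal & !caud & !hipp
  lab[cort] <- codes[["cortex"]]
  lab[caud] <- codes[["caudate_putamen"]]
  lab[thal] <- codes[["thalamus"]]
  lab[hipp] <- codes[["hippocampus"]]
  lab[cereb] <- codes[["cerebellum"]]

  act <- numeric(length(x))
  act[lab == -1L] <- body_activity
  for (nm in BRAIN_REGIONS) act[lab == codes[[nm]]] <- region_activities[[nm]]

  labels <- ifelse(lab > 0L, lab, 0L)
  list(activity = voxel_image(grid, act, activity = TRUE),
       mumap = mu_map(grid, ifelse(body_mask, MU_SOFT_TISSUE, 0)),
       atlas = brain_atlas(grid, labels, codes))
}
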