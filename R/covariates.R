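#' Covariate extraction settings
#'
#' @param buffer_radius_m Radius of the density buffer in meters. The
#'   default, 106 m, is the mean observed step length of the study species
#'   at a 5-minute fix interval, so the buffer covers the habitat reachable
#'   in roughly one step.
#' @param distance_truncation_m Cap (meters) applied to distance-to-feature
#'   values; beyond this range the animal is assumed not to respond to the
#'   feature. Default 1000 m.
#' @return A `covariate_config` list.
#' @export
covariate_config <- function(buffer_radius_m = 106,
                             distance_truncation_m = 1000) {
  if (buffer_radius_m <= 0 || distance_truncation_m <= 0) {
    err_config("buffer radius and distance truncation must be positive")
  }
  structure(list(buffer_radius_m = buffer_radius_m,
                 distance_truncation_m = distance_truncation_m),
            class = "covariate_config")
}

as_points_matrix <- function(points) {
  if (is.data.frame(points)) points <- as.matrix(points)
  if (is.null(dim(points))) points <- matrix(points, ncol = 2, byrow = FALSE)
  storage.mode(points) <- "double"
  if (ncol(points) != 2) err_domain("points must be an n x 2 (x, y) matrix")
  points
}

check_in_extent <- function(stack, pts) {
  if (!all(points_in_extent(stack, pts))) {
    err_domain("point outside raster extent")
  }
}

#' Truncated Euclidean distance to the nearest cell of a feature class
#'
#' Distance is measured from the query point to the nearest cell *center*
#' of the class and capped at `truncation_m`. A point whose own cell
#' belongs to the class is on the feature and gets distance 0.
#'
#' @param stack A `landscape_stack`.
#' @param class_name One schema class name.
#' @param points n x 2 matrix (or data frame) of planar (x, y) in meters.
#' @param truncation_m Distance cap in meters (default 1000).
#' @return Numeric vector of meters, in `[0, truncation_m]`.
#' @export
distance_to <- function(stack, class_name, points, truncation_m = 1000) {
  pts <- as_points_matrix(points)
  check_in_extent(stack, pts)
  mask <- class_mask(stack, class_name)
  d <- dist_to_mask_cpp(pts, mask, stack$origin[1], stack$origin[2],
                        stack$resolution_m, truncation_m)
  # on-feature points are at distance 0 regardless of the center offset
  d[point_in_mask(stack, pts, mask)] <- 0
  d
}

#' Feature density within a circular buffer
#'
#' Density is the number of class cells whose centers fall within
#' `buffer_radius_m` of the point, divided by the area represented by all
#' in-extent cells whose centers fall in the buffer (cell count times cell
#' area). With this clipped denominator a buffer saturated by the class has
#' density exactly `1 / resolution^2` everywhere, including at the raster
#' edge.
#'
#' @inheritParams distance_to
#' @param config A [covariate_config()].
#' @return Numeric vector of densities in pixels per m^2, bounded by
#'   `1 / resolution_m^2`.
#' @export
density_in_buffer <- function(stack, class_name, points,
                              config = covariate_config()) {
  pts <- as_points_matrix(points)
  check_in_extent(stack, pts)
  if (config$buffer_radius_m < stack$resolution_m) {
    err_config("buffer radius must be at least one cell")
  }
  mask <- class_mask(stack, class_name)
  cnt <- buffer_counts_cpp(pts, mask, stack$origin[1], stack$origin[2],
                           stack$resolution_m, config$buffer_radius_m)
  cnt[, 1] / (cnt[, 2] * stack$resolution_m^2)
}

#' Full distance/density covariate matrix at a set of points
#'
#' Computes `dist_<class>` and `dens_<class>` for every class in the
#' stack's schema in one pass (cover classes share a single buffer scan).
#'
#' @inheritParams density_in_buffer
#' @return Numeric matrix, n rows, one `dist_`/`dens_` column pair per
#'   schema class.
#' @export
covariate_matrix <- function(stack, points, config = covariate_config()) {
  pts <- as_points_matrix(points)
  check_in_extent(stack, pts)
  schema <- stack$schema
  covers <- cover_classes(schema)
  overlays <- c(stack$linear_masks, list(stack$pa_mask))
  names(overlays) <- c(linear_classes(schema), pa_class(schema))

  cnt <- cover_density_counts_cpp(
    pts, stack$cover, length(covers), unname(overlays),
    stack$origin[1], stack$origin[2], stack$resolution_m,
    config$buffer_radius_m
  )
  denom <- cnt$total * stack$resolution_m^2
  dens <- cbind(cnt$poly, cnt$overlay) / denom
  colnames(dens) <- paste0("dens_", c(covers, names(overlays)))

  dist <- vapply(schema$class_name, function(cl) {
    distance_to(stack, cl, pts, config$distance_truncation_m)
  }, numeric(nrow(pts)))
  if (nrow(pts) == 1L) dist <- matrix(dist, nrow = 1,
                                      dimnames = list(NULL, schema$class_name))
  colnames(dist) <- paste0("dist_", schema$class_name)

  out <- cbind(dist, dens[, paste0("dens_", schema$class_name), drop = FALSE])
  out
}

#' Scale covariate columns to zero mean and unit variance per individual
#'
#' Standardizes every `dist_`, `dens_`, `lag_dist_` and `lag_dens_` column
#' of a case-control table, centering and scaling within each individual
#' over all used and available rows (models are fitted per individual).
#' Movement-kernel terms (`ln_step_length`, `cos_turn_angle`) are left raw.
#' Zero-variance columns are set to 0 and recorded in the
#' `"zero_variance"` attribute rather than producing NaN.
#'
#' @param table A case-control table (see [generate_available()]).
#' @return The table with scaled covariate columns, `"scaled"` attribute
#'   `TRUE` and `"zero_variance"` attribute listing flagged
#'   individual/column pairs.
#' @export
scale_covariates <- function(table) {
  cols <- grep("^(lag_)?(dist|dens)_", names(table), value = TRUE)
  flagged <- character(0)
  for (id in unique(table$individual_id)) {
    rows <- table$individual_id == id
    for (cl in cols) {
      x <- table[[cl]][rows]
      s <- sd(x)
      if (!is.finite(s) || s < 1e-12) {
        table[[cl]][rows] <- 0
        flagged <- c(flagged, paste(id, cl, sep = ":"))
      } else {
        table[[cl]][rows] <- (x - mean(x)) / s
      }
    }
  }
  attr(table, "scaled") <- TRUE
  attr(table, "zero_variance") <- flagged
  table
}
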