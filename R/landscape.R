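#' Configuration for the synthetic landscape generator
#'
#' @param extent_m Numeric length-2 `(width, height)` of the landscape in
#'   meters. Default 16.2 x 10.2 km (a desk-scale analog of a working
#'   landscape, integral in 30-m cells).
#' @param resolution_m Cell size in meters; must divide both extents.
#'   Default 30 m (Landsat-like).
#' @param seed Integer seed; the generator is fully deterministic given the
#'   config and schema.
#' @param cover_fractions Named numeric vector of target areal fractions for
#'   the polygonal non-protected cover classes; must sum to 1.
#' @param linear_density Named numeric vector of target total length per
#'   km^2 (in km/km^2) for the linear classes.
#' @param pa_count Number of protected-area patches to place.
#' @param pa_mean_area_m2 Mean patch area (m^2) of the log-normal
#'   protected-area size distribution.
#' @param origin Lower-left corner `(x0, y0)` in meters.
#' @param patch_scale_m Correlation length (meters) of the Gaussian random
#'   fields that shape cover patches.
#' @return A `landscape_config` list.
#' @export
landscape_config <- function(extent_m = c(16200, 10200),
                             resolution_m = 30,
                             seed = 1L,
                             cover_fractions = default_cover_fractions(),
                             linear_density = c(streams = 0.4, roads = 0.8,
                                                rail_lines = 0.1),
                             pa_count = 12,
                             pa_mean_area_m2 = 1.6e6,
                             origin = c(0, 0),
                             patch_scale_m = 240) {
  if (length(extent_m) != 2 || any(extent_m <= 0)) {
    err_config("extent_m must be two positive numbers (width, height)")
  }
  if (resolution_m <= 0) err_config("resolution_m must be positive")
  ncells <- extent_m / resolution_m
  if (any(abs(ncells - round(ncells)) > 1e-9)) {
    err_config("resolution_m must divide both extents")
  }
  if (any(cover_fractions < 0 | cover_fractions > 1)) {
    err_config("cover fractions must lie in [0, 1]")
  }
  if (abs(sum(cover_fractions) - 1) > 1e-9) {
    err_config("cover fractions must sum to 1")
  }
  if (pa_count < 0 || pa_mean_area_m2 <= 0) {
    err_config("pa_count must be >= 0 and pa_mean_area_m2 > 0")
  }
  structure(list(
    extent_m = as.numeric(extent_m), resolution_m = resolution_m,
    seed = seed, cover_fractions = cover_fractions,
    linear_density = linear_density, pa_count = pa_count,
    pa_mean_area_m2 = pa_mean_area_m2, origin = as.numeric(origin),
    patch_scale_m = patch_scale_m
  ), class = "landscape_config")
}

#' Default cover fractions for the synthetic working landscape
#'
#' Aspen-parkland-like composition: deciduous-dominated forest interspersed
#' with wetlands, grasslands and an agricultural/developed matrix.
#'
#' @return Named numeric vector over the 11 polygonal cover classes,
#'   summing to 1.
#' @export
default_cover_fractions <- function() {
  c(bare = 0.02, deciduous = 0.28, coniferous = 0.08, mixed = 0.10,
    wetlands = 0.12, grasslands = 0.10, lakes = 0.04, shrubs = 0.06,
    development = 0.05, crops = 0.10, forage = 0.05)
}

# Separable Gaussian smoothing of a matrix (row then column pass with
# normalized banded kernels; edge cells renormalize, so no padding bias).
smooth2d <- function(m, sigma_cells) {
  band <- function(n) {
    K <- outer(seq_len(n), seq_len(n),
               function(i, j) exp(-(i - j)^2 / (2 * sigma_cells^2)))
    K / rowSums(K)
  }
  band(nrow(m)) %*% m %*% t(band(ncol(m)))
}

# Rasterize random polylines until the total drawn length reaches
# target_len_m. Paths advance one cell length per move with persistent
# heading, yielding connected, 1-cell-wide traces.
rasterize_polylines <- function(nr, nc, res, target_len_m) {
  mask <- matrix(FALSE, nr, nc)
  if (target_len_m <= 0) return(mask)
  total <- 0
  while (total < target_len_m) {
    side <- sample.int(4, 1)
    w <- nc * res
    h <- nr * res
    if (side == 1) {       # left edge, heading east-ish
      pos <- c(0, runif(1, 0, h)); heading <- runif(1, -pi / 3, pi / 3)
    } else if (side == 2) { # right edge, heading west-ish
      pos <- c(w, runif(1, 0, h)); heading <- pi + runif(1, -pi / 3, pi / 3)
    } else if (side == 3) { # bottom edge, heading north-ish
      pos <- c(runif(1, 0, w), 0); heading <- pi / 2 + runif(1, -pi / 3, pi / 3)
    } else {               # top edge, heading south-ish
      pos <- c(runif(1, 0, w), h); heading <- -pi / 2 + runif(1, -pi / 3, pi / 3)
    }
    repeat {
      pos <- pos + res * c(cos(heading), sin(heading))
      if (pos[1] < 0 || pos[1] >= w || pos[2] <= 0 || pos[2] > h) break
      cc <- floor(pos[1] / res) + 1L
      rr <- nr - floor(pos[2] / res)
      mask[rr, cc] <- TRUE
      total <- total + res
      heading <- heading + rnorm(1, 0, 0.15)
      if (total >= target_len_m) break
    }
  }
  mask
}

# Protected-area patches: discs or axis-aligned rectangles with log-normal
# areas centered on pa_mean_area_m2, placed uniformly; overlap with any
# cover class (and each other) is allowed.
place_pa_patches <- function(nr, nc, res, count, mean_area_m2) {
  mask <- matrix(FALSE, nr, nc)
  if (count < 1) return(mask)
  xc <- (seq_len(nc) - 0.5) * res
  yc <- (nr - seq_len(nr) + 0.5) * res
  sdl <- 0.4
  for (i in seq_len(count)) {
    area <- rlnorm(1, log(mean_area_m2) - sdl^2 / 2, sdl)
    cx <- runif(1, 0, nc * res)
    cy <- runif(1, 0, nr * res)
    if (runif(1) < 0.5) {
      r <- sqrt(area / pi)
      hit <- outer((yc - cy)^2, (xc - cx)^2, "+") <= r^2
    } else {
      aspect <- exp(runif(1, -0.5, 0.5))
      hw <- sqrt(area * aspect) / 2
      hh <- sqrt(area / aspect) / 2
      hit <- outer(abs(yc - cy) <= hh, abs(xc - cx) <= hw, "&")
    }
    mask <- mask | hit
  }
  mask
}

#' Generate a synthetic heterogeneous landscape
#'
#' Builds a categorical land-cover grid by thresholding smoothed Gaussian
#' random fields (one per polygonal class) with greedy exact-count
#' assignment, so every class hits its target fraction while forming
#' spatially contiguous patches; rasterizes the linear classes as random
#' polylines to a target length density; and overlays a protected-area
#' network of log-normally sized patches. Deterministic given
#' `config$seed`.
#'
#' @param config A [landscape_config()].
#' @param schema A [feature_schema()]; default [default_feature_schema()].
#' @return A `landscape_stack`: list with integer matrix `cover` (codes
#'   index the polygonal cover classes), logical `pa_mask`, named list
#'   `linear_masks`, `origin`, `resolution_m`, and the `schema`.
#' @export
generate_landscape <- function(config, schema = default_feature_schema()) {
  # re-validate even a prebuilt config: fields may have been edited
  config <- do.call(landscape_config, unclass(config))
  covers <- cover_classes(schema)
  unknown <- setdiff(names(config$cover_fractions), covers)
  if (length(unknown)) {
    err_config(paste("cover_fractions name classes not in schema:",
                     paste(unknown, collapse = ", ")))
  }
  res <- config$resolution_m
  nc <- as.integer(round(config$extent_m[1] / res))
  nr <- as.integer(round(config$extent_m[2] / res))
  ncells <- nr * nc

  with_seed(config$seed, {
    frac <- config$cover_fractions[covers]
    frac[is.na(frac)] <- 0
    names(frac) <- covers
    # integer target counts summing exactly to ncells (largest remainders)
    raw <- frac * ncells
    cnt <- floor(raw)
    rem <- ncells - sum(cnt)
    if (rem > 0) {
      up <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
      cnt[up] <- cnt[up] + 1
    }
    cnt[frac == 0] <- 0

    sigma <- max(1, config$patch_scale_m / res)
    fields <- lapply(covers, function(cl) {
      f <- smooth2d(matrix(rnorm(ncells), nr, nc), sigma)
      (f - mean(f)) / sd(f)
    })
    names(fields) <- covers

    cover <- integer(ncells)
    unassigned <- rep(TRUE, ncells)
    for (cl in names(sort(cnt, decreasing = TRUE))) {
      n_cl <- cnt[[cl]]
      if (n_cl == 0) next
      idx <- which(unassigned)
      take <- idx[order(fields[[cl]][idx], decreasing = TRUE)[seq_len(min(n_cl, length(idx)))]]
      cover[take] <- match(cl, covers)
      unassigned[take] <- FALSE
    }
    # numerical safety: any unassigned remainder goes to the largest class
    if (any(unassigned)) {
      cover[unassigned] <- match(names(which.max(cnt)), covers)
    }
    cover <- matrix(cover, nr, nc)

    km2 <- prod(config$extent_m) / 1e6
    linear_masks <- lapply(linear_classes(schema), function(cl) {
      dens <- config$linear_density[[cl]] %||% 0
      rasterize_polylines(nr, nc, res, dens * km2 * 1000)
    })
    names(linear_masks) <- linear_classes(schema)

    pa_mask <- place_pa_patches(nr, nc, res, config$pa_count,
                                config$pa_mean_area_m2)

    structure(list(
      cover = cover, pa_mask = pa_mask, linear_masks = linear_masks,
      origin = config$origin, resolution_m = res, schema = schema,
      config = config
    ), class = "landscape_stack")
  })
}

#' Assemble a landscape stack from raw grids
#'
#' Low-level constructor used when rasters come from elsewhere (or from
#' code in tests): a coded cover matrix, a protected-area mask and one mask
#' per linear class, sharing shape, origin and resolution.
#'
#' @param cover Integer matrix of cover codes (1-based indices into the
#'   schema's polygonal cover classes; row 1 is the top of the map).
#' @param pa_mask Logical matrix, protected-area overlay.
#' @param linear_masks Named list of logical matrices, one per linear
#'   class.
#' @param origin Lower-left corner `(x0, y0)` in meters.
#' @param resolution_m Cell size in meters.
#' @param schema A [feature_schema()].
#' @return A `landscape_stack`.
#' @export
landscape_stack <- function(cover, pa_mask = NULL, linear_masks = NULL,
                            origin = c(0, 0), resolution_m = 30,
                            schema = default_feature_schema()) {
  cover <- matrix(as.integer(cover), nrow(cover), ncol(cover))
  if (any(is.na(cover)) || any(cover < 1) ||
      any(cover > length(cover_classes(schema)))) {
    err_config("cover codes must index the schema's polygonal cover classes")
  }
  if (is.null(pa_mask)) pa_mask <- matrix(FALSE, nrow(cover), ncol(cover))
  if (is.null(linear_masks)) {
    linear_masks <- lapply(linear_classes(schema), function(cl) {
      matrix(FALSE, nrow(cover), ncol(cover))
    })
    names(linear_masks) <- linear_classes(schema)
  }
  for (m in c(list(pa_mask), linear_masks)) {
    if (!identical(dim(m), dim(cover))) {
      err_config("all grids must share the cover grid's shape")
    }
  }
  structure(list(cover = cover, pa_mask = pa_mask,
                 linear_masks = linear_masks, origin = as.numeric(origin),
                 resolution_m = resolution_m, schema = schema),
            class = "landscape_stack")
}

#' @export
print.landscape_stack <- function(x, ...) {
  cat(sprintf(
    "<landscape_stack> %d x %d cells @ %g m (%.1f x %.1f km), %d cover classes, PA fraction %.3f\n",
    nrow(x$cover), ncol(x$cover), x$resolution_m,
    ncol(x$cover) * x$resolution_m / 1000, nrow(x$cover) * x$resolution_m / 1000,
    length(cover_classes(x$schema)), mean(x$pa_mask)
  ))
  invisible(x)
}

# extent as (xmin, xmax, ymin, ymax)
stack_extent <- function(stack) {
  c(stack$origin[1], stack$origin[1] + ncol(stack$cover) * stack$resolution_m,
    stack$origin[2], stack$origin[2] + nrow(stack$cover) * stack$resolution_m)
}

points_in_extent <- function(stack, pts) {
  e <- stack_extent(stack)
  pts[, 1] >= e[1] & pts[, 1] <= e[2] & pts[, 2] >= e[3] & pts[, 2] <= e[4]
}

# logical mask for any schema class
class_mask <- function(stack, class_name) {
  schema <- stack$schema
  if (!class_name %in% schema$class_name) {
    err_schema(paste("unknown feature class:", class_name))
  }
  if (class_name %in% names(stack$linear_masks)) {
    stack$linear_masks[[class_name]]
  } else if (class_name == pa_class(schema)) {
    stack$pa_mask
  } else {
    stack$cover == match(class_name, cover_classes(schema))
  }
}

#' Is a point inside the protected-area overlay?
#'
#' @param stack A `landscape_stack`.
#' @param points n x 2 matrix (or data frame) of planar (x, y) meters.
#' @return Logical vector: the containing cell is part of a protected area.
#' @export
in_protected_area <- function(stack, points) {
  pts <- as_points_matrix(points)
  check_in_extent(stack, pts)
  point_in_mask(stack, pts, stack$pa_mask)
}

# TRUE where each point's containing cell is TRUE in `mask`
point_in_mask <- function(stack, pts, mask) {
  res <- stack$resolution_m
  nr <- nrow(mask)
  cc <- pmin(pmax(floor((pts[, 1] - stack$origin[1]) / res), 0), ncol(mask) - 1) + 1
  rr <- pmin(pmax(floor((stack$origin[2] + nr * res - pts[, 2]) / res), 0), nr - 1) + 1
  mask[cbind(rr, cc)]
}
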