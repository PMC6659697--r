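#' Movement kernel parameters
#'
#' Step lengths are log-normal; turn angles are wrapped normal around a
#' small positive mean, giving the weak forward persistence typical of a
#' directed mustelid at a 5-minute fix interval.
#'
#' @param mean_step_m Marginal mean step length in meters (default 105.47).
#'   `meanlog` is back-solved as `log(mean_step_m) - sdlog^2 / 2` unless
#'   given explicitly.
#' @param sdlog Log-scale standard deviation of step length (default 1).
#' @param turn_mean_rad Mean turn angle in radians (default 0.08).
#' @param turn_sd_rad SD of the (pre-wrap) normal turn proposal (default 1.2).
#' @param fix_interval_s Nominal GPS fix interval in seconds (default 300).
#' @param meanlog Optional explicit log-scale mean, overriding
#'   `mean_step_m`.
#' @return A `movement_params` list.
#' @export
movement_params <- function(mean_step_m = 105.47, sdlog = 1,
                            turn_mean_rad = 0.08, turn_sd_rad = 1.2,
                            fix_interval_s = 300, meanlog = NULL) {
  if (sdlog <= 0 || turn_sd_rad <= 0 || fix_interval_s <= 0) {
    err_config("sdlog, turn_sd_rad and fix_interval_s must be positive")
  }
  ml <- meanlog %||% (log(mean_step_m) - sdlog^2 / 2)
  if (!is.finite(exp(ml + sdlog^2 / 2))) {
    err_config("implied mean step length is not finite")
  }
  structure(list(meanlog = ml, sdlog = sdlog, turn_mean_rad = turn_mean_rad,
                 turn_sd_rad = turn_sd_rad, fix_interval_s = fix_interval_s),
            class = "movement_params")
}

#' Selection (connectivity framework) parameters
#'
#' Controls how simulated animals choose among candidate steps. Candidate
#' choice is softmax over a framework-specific utility, which makes the
#' simulator the exact generative dual of conditional logistic regression.
#'
#' Framework kernels (alpha = `strength`):
#' \describe{
#'   \item{null}{u = 0: uniform choice among candidates.}
#'   \item{corridor}{u = alpha * (sum over `corridor_dens_classes` of
#'     z(dens(end)) * z(dens(previous end)) + sum over linear classes of
#'     z(dist(end)) * z(dist(previous end))), where z standardizes each
#'     covariate by its landscape-wide mean and SD. A positive correlation
#'     between consecutive steps' habitat covariates is the corridor
#'     prediction, and this product form is its exact softmax dual: the
#'     corridor model's current-by-previous interaction terms are the
#'     generating utility.}
#'   \item{lcp}{u = -alpha * sum(cost_f * dens_f(end)) over the costed
#'     classes (negative costs mark preferred, high-residency cover); in
#'     addition, proposals lengthen (`meanlog + lcp_len_gain * R`) and
#'     straighten (`turn_sd * exp(-lcp_turn_calm * R)`) with the local
#'     cost-weighted density R -- fast, linear transit through resistant
#'     cover, short tortuous residency steps in preferred cover -- per the
#'     least-cost-path prediction that feature density covaries with step
#'     length and (inversely) tortuosity.}
#'   \item{stepping_stone}{u = alpha * 1(end in protected area); proposals
#'     inside protected areas shrink by `pa_step_scale` and widen their
#'     turn SD by `pa_turn_widen` (high residency inside patches, linear
#'     transits between).}
#' }
#'
#' @param framework One of `"null"`, `"corridor"`, `"lcp"`,
#'   `"stepping_stone"`.
#' @param strength Selection strength alpha (>= 0). `NULL` picks a moderate
#'   framework-specific default: 0 for null, 0.5 for corridor (per
#'   standardized product term), 2000 for lcp (on the raw pixels/m^2
#'   density scale), 2 for stepping_stone (log-odds of a protected
#'   endpoint).
#' @param n_candidates Number of candidate steps per move (K >= 2,
#'   default 20).
#' @param corridor_dens_classes Polygonal classes whose density similarity
#'   drives the corridor kernel (default the forest trio).
#' @param class_costs Named costs for the lcp kernel; default puts
#'   resistance on open and anthropogenic cover.
#' @param pa_step_scale Multiplier in (0, 1] on step length proposals
#'   inside protected areas (stepping_stone only).
#' @param pa_turn_widen Multiplier >= 1 on turn SD inside protected areas
#'   (stepping_stone only).
#' @param lcp_len_gain Added to `meanlog` per unit normalized local
#'   resistance (lcp only).
#' @param lcp_turn_calm Scales turn SD by `exp(-calm * resistance)`
#'   (lcp only).
#' @param distance_cap_m Truncation (meters) applied when the kernel reads
#'   linear-feature distances.
#' @return A `selection_params` list.
#' @export
selection_params <- function(framework = c("null", "corridor", "lcp",
                                           "stepping_stone"),
                             strength = NULL, n_candidates = 20,
                             corridor_dens_classes = c("deciduous",
                                                       "coniferous", "mixed"),
                             class_costs = NULL,
                             pa_step_scale = 0.5, pa_turn_widen = 2,
                             lcp_len_gain = 1.5, lcp_turn_calm = 2,
                             distance_cap_m = 1000) {
  framework <- match.arg(framework)
  if (is.null(strength)) {
    strength <- switch(framework, null = 0, corridor = 0.5, lcp = 2000,
                       stepping_stone = 2)
  }
  if (strength < 0) err_config("strength must be >= 0")
  if (n_candidates < 2) err_config("n_candidates must be >= 2")
  if (pa_step_scale <= 0 || pa_step_scale > 1) {
    err_config("pa_step_scale must be in (0, 1]")
  }
  if (pa_turn_widen < 1) err_config("pa_turn_widen must be >= 1")
  if (is.null(class_costs)) {
    class_costs <- c(deciduous = -0.5, coniferous = -0.5, mixed = -0.5,
                     development = 1, crops = 1, forage = 0.7,
                     grasslands = 0.5, bare = 0.5, shrubs = 0.3)
  }
  structure(list(framework = framework, strength = strength,
                 n_candidates = n_candidates,
                 corridor_dens_classes = corridor_dens_classes,
                 class_costs = class_costs,
                 pa_step_scale = pa_step_scale, pa_turn_widen = pa_turn_widen,
                 lcp_len_gain = lcp_len_gain, lcp_turn_calm = lcp_turn_calm,
                 distance_cap_m = distance_cap_m),
            class = "selection_params")
}

#' Utility of one candidate step under a connectivity framework
#'
#' Scalar form of the kernel documented in [selection_params()]; the
#' simulator uses a vectorized internal equivalent. Covariate vectors are
#' named (`dist_<class>`, `dens_<class>`) as returned by
#' [covariate_matrix()].
#'
#' @param framework Framework name.
#' @param current_covariates Named covariates at the candidate end point.
#' @param previous_covariates Named covariates at the previous end point.
#' @param proposed_step Numeric `(length_m, turn_rad)` of the candidate
#'   (part of the proposal, not the utility, for every built-in kernel).
#' @param params A [selection_params()].
#' @param schema Feature schema used to group classes.
#' @param moments Optional standardization moments (a list with named
#'   numeric vectors `mean` and `sd` over covariate columns) used by the
#'   corridor kernel; see [landscape_moments()]. Without them covariates
#'   enter the products raw.
#' @return A single finite utility value.
#' @export
candidate_utility <- function(framework, current_covariates,
                              previous_covariates, proposed_step, params,
                              schema = default_feature_schema(),
                              moments = NULL) {
  cur <- unlist(current_covariates)
  prev <- unlist(previous_covariates)
  a <- params$strength
  switch(framework,
    null = 0,
    corridor = {
      cols <- c(paste0("dens_", params$corridor_dens_classes),
                paste0("dist_", linear_classes(schema)))
      z <- function(v) {
        if (is.null(moments)) v[cols]
        else (v[cols] - moments$mean[cols]) / moments$sd[cols]
      }
      a * sum(z(cur) * z(prev))
    },
    lcp = {
      costs <- params$class_costs
      -a * sum(costs * cur[paste0("dens_", names(costs))])
    },
    stepping_stone = {
      a * as.numeric(cur[["dist_protected_areas"]] == 0)
    },
    err_config(paste("unknown framework:", framework))
  )
}

#' Landscape-wide covariate moments for standardization
#'
#' Mean and standard deviation of each `dist_`/`dens_` covariate over a
#' regular subsample of cell centers (at most `max_side` per dimension);
#' deterministic. Used by the corridor kernel to put its product terms on a
#' standardized scale.
#'
#' @param stack A `landscape_stack`.
#' @param config A [covariate_config()].
#' @param max_side Maximum sample points per dimension (default 48).
#' @return List with named vectors `mean` and `sd`.
#' @export
landscape_moments <- function(stack, config = covariate_config(),
                              max_side = 48) {
  nr <- nrow(stack$cover)
  nc <- ncol(stack$cover)
  res <- stack$resolution_m
  rs <- unique(round(seq(1, nr, length.out = min(nr, max_side))))
  cs <- unique(round(seq(1, nc, length.out = min(nc, max_side))))
  xs <- stack$origin[1] + (cs - 0.5) * res
  ys <- stack$origin[2] + (nr - rs + 0.5) * res
  pts <- cbind(rep(xs, each = length(ys)), rep(ys, length(xs)))
  cm <- covariate_matrix(stack, pts, config)
  sds <- apply(cm, 2, sd)
  sds[sds < 1e-12] <- 1
  list(mean = colMeans(cm), sd = sds)
}

# local resistance in [0, ~1]: cost-weighted density at a point, normalized
# by the saturated single-class density 1/res^2
local_resistance <- function(stack, pts, costs, config) {
  dens <- vapply(names(costs), function(cl) {
    density_in_buffer(stack, cl, pts, config)
  }, numeric(nrow(pts)))
  if (nrow(pts) == 1L) dens <- matrix(dens, nrow = 1)
  as.vector(dens %*% costs) * stack$resolution_m^2
}

#' Simulate a GPS track under a connectivity framework
#'
#' Biased correlated random walk: at each fix, `K` candidate steps are
#' drawn from the movement kernel (log-normal length, wrapped-normal turn
#' relative to the current heading), candidates leaving the landscape are
#' redrawn (up to 100 rounds, then truncated to the boundary with a
#' warning), and one candidate is selected with probability proportional to
#' `exp(utility)`. With `strength = 0` every framework reduces to an
#' unbiased correlated random walk.
#'
#' @param stack A `landscape_stack`.
#' @param move A [movement_params()].
#' @param select A [selection_params()].
#' @param n_fixes Number of GPS fixes (>= 3).
#' @param seed Integer seed; tracks are deterministic given all inputs.
#' @param start Numeric `(x, y)` start location; default the landscape
#'   center.
#' @param individual_id Label for the simulated animal.
#' @param start_time POSIXct of the first fix.
#' @param dropout_rate Probability that any interior fix is dropped
#'   (simulates missed fixes; exercises burst splitting downstream).
#' @return A `track` data frame: `individual_id`, `timestamp` (UTC), `x`,
#'   `y`.
#' @export
simulate_track <- function(stack, move = movement_params(),
                           select = selection_params("null"),
                           n_fixes = 1000, seed = 1L, start = NULL,
                           individual_id = "sim1",
                           start_time = as.POSIXct("2020-01-01",
                                                   tz = "UTC"),
                           dropout_rate = 0) {
  if (n_fixes < 3) err_config("n_fixes must be >= 3")
  e <- stack_extent(stack)
  if (is.null(start)) start <- c(mean(e[1:2]), mean(e[3:4]))
  if (start[1] < e[1] || start[1] > e[2] || start[2] < e[3] ||
      start[2] > e[4]) {
    err_domain("start location outside raster extent")
  }
  cfg <- covariate_config(distance_truncation_m = select$distance_cap_m)
  fw <- select$framework
  alpha <- select$strength
  K <- select$n_candidates
  schema <- stack$schema

  # lean covariate columns for the corridor kernel, standardized by
  # landscape-wide moments
  if (fw == "corridor" && alpha > 0) {
    cor_cols <- c(paste0("dens_", select$corridor_dens_classes),
                  paste0("dist_", linear_classes(schema)))
    mom <- landscape_moments(stack, cfg)
    corridor_z <- function(pts) {
      v <- vapply(cor_cols, function(col) {
        cl <- sub("^(dens|dist)_", "", col)
        if (startsWith(col, "dens_")) {
          density_in_buffer(stack, cl, pts, cfg)
        } else {
          distance_to(stack, cl, pts, select$distance_cap_m)
        }
      }, numeric(nrow(pts)))
      if (nrow(pts) == 1L) v <- matrix(v, nrow = 1, dimnames = list(NULL, cor_cols))
      sweep(sweep(v, 2, mom$mean[cor_cols]), 2, mom$sd[cor_cols], "/")
    }
  }

  with_seed(seed, {
    xs <- numeric(n_fixes)
    ys <- numeric(n_fixes)
    xs[1] <- start[1]
    ys[1] <- start[2]
    heading <- runif(1, -pi, pi)
    prev_cov <- NULL
    truncated <- 0L

    for (t in 2:n_fixes) {
      ml <- move$meanlog
      tsd <- move$turn_sd_rad
      pos <- c(xs[t - 1], ys[t - 1])

      if (fw == "stepping_stone" &&
          point_in_mask(stack, matrix(pos, 1), stack$pa_mask)) {
        ml <- ml + log(select$pa_step_scale)
        tsd <- tsd * select$pa_turn_widen
      } else if (fw == "lcp" && alpha > 0) {
        r <- local_resistance(stack, matrix(pos, 1), select$class_costs, cfg)
        ml <- ml + select$lcp_len_gain * r
        tsd <- tsd * exp(-select$lcp_turn_calm * r)
      }

      len <- rlnorm(K, ml, move$sdlog)
      turn <- wrap_to_pi(rnorm(K, move$turn_mean_rad, tsd))
      hd <- heading + turn
      ex <- pos[1] + len * cos(hd)
      ey <- pos[2] + len * sin(hd)

      bad <- ex < e[1] | ex > e[2] | ey < e[3] | ey > e[4]
      tries <- 0L
      while (any(bad) && tries < 100L) {
        nb <- sum(bad)
        len[bad] <- rlnorm(nb, ml, move$sdlog)
        turn[bad] <- wrap_to_pi(rnorm(nb, move$turn_mean_rad, tsd))
        hd <- heading + turn
        ex[bad] <- pos[1] + len[bad] * cos(hd[bad])
        ey[bad] <- pos[2] + len[bad] * sin(hd[bad])
        bad <- ex < e[1] | ex > e[2] | ey < e[3] | ey > e[4]
        tries <- tries + 1L
      }
      if (any(bad)) {
        ex[bad] <- pmin(pmax(ex[bad], e[1]), e[2])
        ey[bad] <- pmin(pmax(ey[bad], e[3]), e[4])
        truncated <- truncated + sum(bad)
      }

      if (alpha == 0 || fw == "null") {
        j <- sample.int(K, 1)
      } else {
        ends <- cbind(ex, ey)
        cm_step <- NULL
        if (fw == "stepping_stone") {
          u <- alpha * point_in_mask(stack, ends, stack$pa_mask)
        } else if (fw == "corridor") {
          if (is.null(prev_cov)) prev_cov <- corridor_z(matrix(pos, 1))[1, ]
          cm_step <- corridor_z(ends)
          u <- alpha * as.vector(cm_step %*% prev_cov)
        } else { # lcp
          u <- -alpha * local_resistance(stack, ends, select$class_costs,
                                         cfg) / stack$resolution_m^2
        }
        p <- exp(u - max(u))
        j <- sample.int(K, 1, prob = p)
        if (!is.null(cm_step)) prev_cov <- cm_step[j, ]
      }
      xs[t] <- ex[j]
      ys[t] <- ey[j]
      heading <- atan2(ys[t] - ys[t - 1], xs[t] - xs[t - 1])
    }
    if (truncated > 0) {
      warning(sprintf("%d candidate step(s) truncated to the landscape boundary",
                      truncated))
    }

    keep <- rep(TRUE, n_fixes)
    if (dropout_rate > 0) {
      drop <- runif(n_fixes) < dropout_rate
      drop[c(1, n_fixes)] <- FALSE
      keep <- !drop
    }
    out <- data.frame(
      individual_id = individual_id,
      timestamp = start_time + (seq_len(n_fixes) - 1) * move$fix_interval_s,
      x = xs, y = ys, stringsAsFactors = FALSE
    )[keep, , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("track", "data.frame")
    out
  })
}
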