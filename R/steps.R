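#' Derive movement steps from a GPS track
#'
#' A step is the straight line between successive fixes. Gaps longer than
#' 1.5 times the nominal fix interval split the track into bursts; the
#' turn angle of the first step of each burst is undefined (no previous
#' heading) and such steps are excluded from strata downstream. Zero-length
#' steps are dropped with a warning (their log length and heading are
#' undefined).
#'
#' @param track A `track` data frame (`individual_id`, `timestamp`, `x`,
#'   `y`); several individuals may be stacked.
#' @param nominal_interval_s Nominal fix interval in seconds (default 300).
#' @return A `step_series` data frame: per step `individual_id`,
#'   `burst_id`, `step_id`, start/end coordinates, `length_m`,
#'   `heading_rad`, `turn_rad` (NA for the first step of a burst),
#'   `cos_turn`, `ln_length`.
#' @export
derive_steps <- function(track, nominal_interval_s = 300) {
  if (nrow(track) < 3) err_data("need at least 3 fixes to derive steps")
  pieces <- lapply(split(track, track$individual_id), function(tr) {
    tr <- tr[order(tr$timestamp), ]
    if (nrow(tr) < 3) err_data("need at least 3 fixes per individual")
    n <- nrow(tr)
    dt <- as.numeric(difftime(tr$timestamp[-1], tr$timestamp[-n],
                              units = "secs"))
    # fix-level bursts: a gap > 1.5x nominal invalidates the spanning step
    fburst <- cumsum(c(1L, dt > 1.5 * nominal_interval_s))
    valid <- fburst[-n] == fburst[-1]
    dx <- diff(tr$x)
    dy <- diff(tr$y)
    len <- sqrt(dx^2 + dy^2)
    heading <- atan2(dy, dx)
    st <- data.frame(
      individual_id = tr$individual_id[1],
      burst_id = fburst[-n],
      step_id = seq_len(n - 1),
      t_start = tr$timestamp[-n],
      start_x = tr$x[-n], start_y = tr$y[-n],
      end_x = tr$x[-1], end_y = tr$y[-1],
      length_m = len, heading_rad = heading,
      stringsAsFactors = FALSE
    )
    st <- st[valid, , drop = FALSE]
    zero <- st$length_m == 0
    if (any(zero)) {
      warning(sprintf("dropping %d zero-length step(s) (log length undefined)",
                      sum(zero)))
      st <- st[!zero, , drop = FALSE]
    }
    prev_head <- c(NA_real_, st$heading_rad[-nrow(st)])
    prev_head[c(TRUE, diff(st$burst_id) != 0)] <- NA_real_
    st$turn_rad <- wrap_to_pi(st$heading_rad - prev_head)
    st$cos_turn <- cos(st$turn_rad)
    st$ln_length <- log(st$length_m)
    st$prev_heading_rad <- prev_head
    st
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  class(out) <- c("step_series", "data.frame")
  out
}

#' Fit a per-individual log-normal step-length distribution
#'
#' Log-normal maximum likelihood on the used step lengths: `meanlog` is the
#' mean of the log lengths and `sdlog` their sample (n-1) standard
#' deviation.
#'
#' @param steps A `step_series` (one individual's used steps).
#' @return A `step_distribution` list: `meanlog`, `sdlog`, `n`.
#' @export
fit_step_distribution <- function(steps) {
  len <- steps$length_m[steps$length_m > 0]
  if (length(len) < 10) {
    err_data("need at least 10 positive step lengths to fit")
  }
  lg <- log(len)
  s <- sd(lg)
  if (!is.finite(s) || s <= 0) {
    err_data("degenerate step lengths: sdlog must be > 0")
  }
  structure(list(meanlog = mean(lg), sdlog = s, n = length(len)),
            class = "step_distribution")
}

#' Generate the used/available case-control design (geometry only)
#'
#' For every used step with a defined previous heading, draws `k` available
#' steps from the same start point: lengths from the fitted per-individual
#' log-normal, turn angles uniform on (-pi, pi] relative to the previous
#' used heading. Available endpoints falling outside the landscape are
#' redrawn (up to 100 rounds) and finally clamped to the boundary with a
#' warning, preserving the fixed 1:k design.
#'
#' @param steps A `step_series`.
#' @param dist A [fit_step_distribution()] result.
#' @param k Number of available steps per used step (default 10).
#' @param seed Integer seed.
#' @param stack A `landscape_stack` providing the valid extent.
#' @return A `case_control_table` data frame with one `case = 1` row and
#'   `k` `case = 0` rows per stratum; geometry and movement transforms
#'   only (see [attach_covariates()]).
#' @export
generate_available <- function(steps, dist, k = 10, seed = 1L, stack) {
  if (k < 1) err_config("k must be >= 1")
  use <- !is.na(steps$turn_rad) & steps$length_m > 0
  st <- steps[use, , drop = FALSE]
  if (nrow(st) == 0) err_data("no usable steps (none has a previous heading)")
  n <- nrow(st)
  e <- stack_extent(stack)

  with_seed(seed, {
    len <- matrix(rlnorm(n * k, dist$meanlog, dist$sdlog), n, k)
    turn <- matrix(runif(n * k, -pi, pi), n, k)
    hd <- st$prev_heading_rad + turn
    ex <- st$start_x + len * cos(hd)
    ey <- st$start_y + len * sin(hd)

    bad <- ex < e[1] | ex > e[2] | ey < e[3] | ey > e[4]
    tries <- 0L
    while (any(bad) && tries < 100L) {
      nb <- sum(bad)
      len[bad] <- rlnorm(nb, dist$meanlog, dist$sdlog)
      turn[bad] <- runif(nb, -pi, pi)
      hd <- st$prev_heading_rad + turn
      ex[bad] <- (st$start_x + len * cos(hd))[bad]
      ey[bad] <- (st$start_y + len * sin(hd))[bad]
      bad <- ex < e[1] | ex > e[2] | ey < e[3] | ey > e[4]
      tries <- tries + 1L
    }
    if (any(bad)) {
      warning(sprintf("clamping %d available endpoint(s) to the boundary",
                      sum(bad)))
      ex <- pmin(pmax(ex, e[1]), e[2])
      ey <- pmin(pmax(ey, e[3]), e[4])
      clen <- sqrt((ex - st$start_x)^2 + (ey - st$start_y)^2)
      chd <- atan2(ey - st$start_y, ex - st$start_x)
      len[bad] <- clen[bad]
      turn[bad] <- wrap_to_pi(chd - st$prev_heading_rad)[bad]
    }

    stratum <- paste(st$individual_id, st$step_id, sep = "_")
    used <- data.frame(
      stratum_id = stratum, case = 1L, individual_id = st$individual_id,
      step_id = st$step_id,
      start_x = st$start_x, start_y = st$start_y,
      end_x = st$end_x, end_y = st$end_y,
      length_m = st$length_m, turn_rad = st$turn_rad,
      stringsAsFactors = FALSE
    )
    avail <- data.frame(
      stratum_id = rep(stratum, k), case = 0L,
      individual_id = rep(st$individual_id, k),
      step_id = rep(st$step_id, k),
      start_x = rep(st$start_x, k), start_y = rep(st$start_y, k),
      end_x = as.vector(ex), end_y = as.vector(ey),
      length_m = as.vector(len), turn_rad = as.vector(turn),
      stringsAsFactors = FALSE
    )
    out <- rbind(used, avail)
    out <- out[order(match(out$stratum_id, stratum), -out$case), ]
    out$ln_step_length <- log(out$length_m)
    out$cos_turn_angle <- cos(out$turn_rad)
    rownames(out) <- NULL
    attr(out, "k") <- k
    class(out) <- c("case_control_table", "data.frame")
    out
  })
}

#' Attach landscape covariates to a case-control table
#'
#' Adds `dist_<class>` and `dens_<class>` for every schema class at each
#' candidate end point, plus `lag_dist_<class>` / `lag_dens_<class>`
#' evaluated at the previous used step's end point (the stratum's shared
#' start), identical across all rows of a stratum by construction.
#'
#' @param table A `case_control_table` from [generate_available()].
#' @param stack A `landscape_stack`.
#' @param cov_config A [covariate_config()].
#' @return The table with covariate and lagged-covariate columns.
#' @export
attach_covariates <- function(table, stack,
                              cov_config = covariate_config()) {
  ends <- cbind(table$end_x, table$end_y)
  if (!all(points_in_extent(stack, ends))) {
    stop("internal error: case-control endpoint outside raster extent")
  }
  cm <- covariate_matrix(stack, ends, cov_config)

  first <- !duplicated(table$stratum_id)
  starts <- cbind(table$start_x[first], table$start_y[first])
  lag <- covariate_matrix(stack, starts, cov_config)
  lag <- lag[match(table$stratum_id, table$stratum_id[first]), , drop = FALSE]
  colnames(lag) <- paste0("lag_", colnames(lag))

  out <- cbind(table, as.data.frame(cm), as.data.frame(lag))
  attr(out, "k") <- attr(table, "k")
  class(out) <- c("case_control_table", "data.frame")
  out
}

# integrity check used by readers and the fit stage
validate_case_control <- function(table, k = NULL) {
  cases <- tapply(table$case, table$stratum_id, sum)
  if (any(cases != 1)) {
    err_format(sprintf("stratum integrity violated: stratum %s has %d case rows",
                       names(cases)[cases != 1][1], cases[cases != 1][1]))
  }
  sizes <- table(table$stratum_id)
  if (!is.null(k) && any(sizes != k + 1)) {
    err_format("stratum sizes do not match the declared 1:k design")
  }
  invisible(TRUE)
}
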