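# Telemetry, case-control and configuration I/O.

#' Read telemetry CSV
#'
#' Expects columns `individual_id`, `timestamp` (ISO-8601, parsed as UTC,
#' or numeric seconds), `x`, `y` (planar meters). Fixes are sorted per
#' individual by timestamp (with a warning if the input was not monotone);
#' duplicate timestamps within an individual are an error.
#'
#' @param path CSV file path.
#' @return Named list of `track` data frames, one per individual.
#' @export
read_telemetry <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual_id", "timestamp", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    err_format(paste("telemetry file is missing column(s):",
                     paste(miss, collapse = ", ")))
  }
  if (is.numeric(df$timestamp)) {
    ts <- as.POSIXct(df$timestamp, origin = "1970-01-01", tz = "UTC")
  } else {
    ts <- as.POSIXct(rep(NA_real_, nrow(df)), origin = "1970-01-01",
                     tz = "UTC")
    for (fmt in c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d")) {
      idx <- is.na(ts)
      if (!any(idx)) break
      ts[idx] <- as.POSIXct(strptime(df$timestamp[idx], fmt, tz = "UTC"))
    }
    bad <- which(is.na(ts) & !is.na(df$timestamp))
    if (length(bad)) {
      err_format(sprintf("unparseable timestamp at data row %d: '%s'",
                         bad[1], df$timestamp[bad[1]]))
    }
  }
  df$timestamp <- ts
  tracks <- lapply(split(df, df$individual_id), function(tr) {
    dup <- duplicated(tr$timestamp)
    if (any(dup)) {
      err_format(sprintf(
        "duplicated timestamp for individual %s at data row %d",
        tr$individual_id[1], which(df$individual_id == tr$individual_id[1])[which(dup)[1]]))
    }
    if (is.unsorted(tr$timestamp)) {
      warning(sprintf("fixes for individual %s were not time-ordered; sorting",
                      tr$individual_id[1]))
      tr <- tr[order(tr$timestamp), ]
    }
    rownames(tr) <- NULL
    class(tr) <- c("track", "data.frame")
    tr
  })
  tracks
}

#' Write telemetry CSV
#'
#' @param tracks A `track` data frame or list of them.
#' @param path Output file.
#' @export
write_telemetry <- function(tracks, path) {
  if (is.data.frame(tracks)) tracks <- list(tracks)
  df <- do.call(rbind, lapply(tracks, as.data.frame))
  df$timestamp <- format(df$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  write.csv(df[, c("individual_id", "timestamp", "x", "y")], path,
            row.names = FALSE)
  invisible(path)
}

#' Write / read a case-control covariate table
#'
#' The CSV carries one row per (stratum, candidate) with the case
#' indicator, movement transforms and all current plus lagged covariates.
#' Reading validates stratum integrity (exactly one case row per stratum).
#'
#' @param table A `case_control_table`.
#' @param path CSV file.
#' @export
write_case_control <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_case_control
#' @export
read_case_control <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("stratum_id", "case", "individual_id", "ln_step_length",
            "cos_turn_angle")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    err_format(paste("case-control file is missing column(s):",
                     paste(miss, collapse = ", ")))
  }
  class(df) <- c("case_control_table", "data.frame")
  validate_case_control(df)
  df
}

#' Assemble a full run configuration
#'
#' One global `seed` deterministically drives every random stage through
#' [derive_seed()].
#'
#' @param seed Global integer seed.
#' @param n_individuals Number of simulated animals.
#' @param n_fixes GPS fixes per animal.
#' @param framework Connectivity framework generating the tracks.
#' @param landscape A [landscape_config()].
#' @param movement A [movement_params()].
#' @param selection A [selection_params()]; defaults to the requested
#'   framework.
#' @param k Available steps per used step.
#' @param covariates A [covariate_config()].
#' @param collinearity_threshold Screen threshold for the global model.
#' @param output_dir Where [run_pipeline()] writes artifacts.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, n_individuals = 2, n_fixes = 500,
                       framework = "corridor",
                       landscape = landscape_config(seed = derive_seed(seed, "landscape")),
                       movement = movement_params(),
                       selection = selection_params(framework),
                       k = 10,
                       covariates = covariate_config(),
                       collinearity_threshold = 0.7,
                       output_dir = tempfile("issaconn_run")) {
  structure(list(
    seed = seed, n_individuals = n_individuals, n_fixes = n_fixes,
    landscape = landscape, movement = movement, selection = selection,
    sampling = list(k = k, seed = derive_seed(seed, "available")),
    covariates = covariates,
    competition = list(collinearity_threshold = collinearity_threshold),
    output_dir = output_dir
  ), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' The YAML mirrors the [run_config()] argument names; nested blocks
#' `landscape`, `movement`, `selection`, `covariates` mirror the
#' corresponding constructor arguments.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  seed <- y$seed %||% 1L
  ls_args <- y$landscape %||% list()
  if (!is.null(ls_args$cover_fractions)) {
    ls_args$cover_fractions <- unlist(ls_args$cover_fractions)
  }
  if (!is.null(ls_args$linear_density)) {
    ls_args$linear_density <- unlist(ls_args$linear_density)
  }
  ls_args$seed <- ls_args$seed %||% derive_seed(seed, "landscape")
  sel_args <- y$selection %||% list()
  sel_args$framework <- sel_args$framework %||% (y$framework %||% "corridor")
  if (!is.null(sel_args$class_costs)) {
    sel_args$class_costs <- unlist(sel_args$class_costs)
  }
  run_config(
    seed = seed,
    n_individuals = y$n_individuals %||% 2,
    n_fixes = y$n_fixes %||% 500,
    framework = sel_args$framework,
    landscape = do.call(landscape_config, ls_args),
    movement = do.call(movement_params, y$movement %||% list()),
    selection = do.call(selection_params, sel_args),
    k = y$k %||% 10,
    covariates = do.call(covariate_config, y$covariates %||% list()),
    collinearity_threshold = y$collinearity_threshold %||% 0.7,
    output_dir = y$output_dir %||% tempfile("issaconn_run")
  )
}

# short stable content hash (FNV-1a over the serialized JSON) for manifests
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                        force = TRUE)
  bytes <- utf8ToInt(as.character(s))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483647))
}
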