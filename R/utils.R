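# Shared internal helpers: classed errors, seeded evaluation, angle wrapping.

issa_error <- function(msg, class) {
  stop(structure(
    class = c(class, "issaconn_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

err_config <- function(msg) issa_error(msg, "issaconn_config_error")
err_domain <- function(msg) issa_error(msg, "issaconn_domain_error")
err_schema <- function(msg) issa_error(msg, "issaconn_schema_error")
err_format <- function(msg) issa_error(msg, "issaconn_format_error")
err_data   <- function(msg) issa_error(msg, "issaconn_data_error")
err_design <- function(msg) issa_error(msg, "issaconn_design_error")

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    err_config("seed must be a single finite number")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage-specific sub-seed from a single run seed
#'
#' Pure function mapping a global seed and a stage index to a reproducible
#' sub-seed below 2^31, so one user-facing seed drives every random stage of
#' the pipeline without hidden global state.
#'
#' @param seed Integer global seed.
#' @param stage Integer stage index (>= 0) or one of the named pipeline
#'   stages `"landscape"`, `"tracks"`, `"available"`.
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, stage) {
  if (is.character(stage)) {
    stage <- match(stage, c("landscape", "tracks", "available"))
    if (is.na(stage)) err_config("unknown pipeline stage name")
  }
  ((as.double(seed) %% 2147483647) * 1000003 + stage * 7919) %% 2147483647
}

# Wrap angles into (-pi, pi].
wrap_to_pi <- function(a) {
  w <- a - 2 * pi * floor((a + pi) / (2 * pi))
  w[w <= -pi] <- pi
  w
}

`%||%` <- function(a, b) if (is.null(a)) b else a
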