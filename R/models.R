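#' Model specification for one connectivity hypothesis
#'
#' Terms are main effects (a covariate column name) or interactions
#' (`"a:b"`, the elementwise product of two columns).
#'
#' @param name Model name.
#' @param terms Character vector of term labels.
#' @return A `model_spec`.
#' @export
model_spec <- function(name, terms) {
  if (anyDuplicated(terms)) err_config("duplicate terms in model spec")
  structure(list(name = name, terms = terms), class = "model_spec")
}

#' Core iSSA habitat-selection terms
#'
#' Movement kernel (cosine turn angle, log step length) plus distance to
#' and density of the forest classes the focal species selects, and
#' distance to wetlands.
#'
#' @return Character vector of 9 term labels.
#' @export
core_terms <- function() {
  c("cos_turn_angle", "ln_step_length",
    "dist_deciduous", "dens_deciduous",
    "dist_coniferous", "dens_coniferous",
    "dist_mixed", "dens_mixed",
    "dist_wetlands")
}

#' Build the five-hypothesis candidate model set
#'
#' Returns the core habitat model plus the corridor, least-cost-path,
#' stepping-stone and global models, all containing the core terms:
#' \describe{
#'   \item{core}{movement kernel + forest selection (see [core_terms()]).}
#'   \item{corridor}{core + `dens_f:lag_dens_f` for the core polygonal
#'     classes and `dist_f:lag_dist_f` for the linear classes --
#'     between-step structural similarity.}
#'   \item{lcp}{core + `dens_f:ln_step_length` and `dens_f:cos_turn_angle`
#'     for the core polygonal classes -- density-dependent speed and
#'     tortuosity.}
#'   \item{stepping_stone}{core + protected-area distance/density and
#'     their interactions with the movement kernel and the previous step's
#'     protected-area density.}
#'   \item{global}{union of all terms, screened for pairwise collinearity.}
#' }
#'
#' Lagged ("previous step") effects appear only inside current-by-previous
#' interactions: a pure lagged main effect is constant within a stratum and
#' structurally inestimable under exact conditioning.
#'
#' @param schema A [feature_schema()].
#' @param collinearity_threshold Pairwise `|r|` at or above which the
#'   later-listed of two global-model term columns is dropped (default
#'   0.7).
#' @param table Optional scaled case-control table used for the
#'   collinearity screen; without it the global model keeps the full
#'   union.
#' @return Named list of five `model_spec`s.
#' @export
build_candidate_set <- function(schema = default_feature_schema(),
                                collinearity_threshold = 0.7,
                                table = NULL) {
  forest <- c("deciduous", "coniferous", "mixed")
  need <- c(forest, "wetlands")
  if (!all(need %in% schema$class_name)) {
    err_schema(paste("schema is missing class(es):",
                     paste(setdiff(need, schema$class_name), collapse = ", ")))
  }
  pa <- pa_class(schema)
  lin <- linear_classes(schema)

  core <- core_terms()
  corridor <- c(core,
                paste0("dens_", forest, ":lag_dens_", forest),
                paste0("dist_", lin, ":lag_dist_", lin))
  lcp <- c(core,
           paste0("dens_", forest, ":ln_step_length"),
           paste0("dens_", forest, ":cos_turn_angle"))
  stepping <- c(core,
                paste0("dist_", pa), paste0("dens_", pa),
                paste0("dens_", pa, ":ln_step_length"),
                paste0("dens_", pa, ":cos_turn_angle"),
                paste0("dens_", pa, ":lag_dens_", pa))
  global <- unique(c(core, corridor, lcp, stepping))

  if (!is.null(table)) {
    cols <- lapply(global, function(tm) {
      parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
      Reduce(`*`, lapply(parts, function(p) table[[p]]))
    })
    M <- do.call(cbind, cols)
    colnames(M) <- global
    keep <- rep(TRUE, length(global))
    # movement kernel terms are listed first and therefore always retained
    for (j in seq_along(global)) {
      if (!keep[j]) next
      for (i in seq_len(j - 1)) {
        if (!keep[i]) next
        r <- suppressWarnings(cor(M[, i], M[, j]))
        if (is.finite(r) && abs(r) >= collinearity_threshold) {
          keep[j] <- FALSE
          break
        }
      }
    }
    global <- global[keep]
  }

  list(core = model_spec("core", core),
       corridor = model_spec("corridor", corridor),
       lcp = model_spec("lcp", lcp),
       stepping_stone = model_spec("stepping_stone", stepping),
       global = model_spec("global", global))
}

#' Akaike weights
#'
#' `w_i = exp(-delta_i / 2) / sum_j exp(-delta_j / 2)` with
#' `delta_i = AIC_i - min(AIC)`.
#'
#' @param aics Numeric vector of AIC values.
#' @return Weights summing to 1.
#' @export
akaike_weights <- function(aics) {
  if (length(aics) < 1 || any(!is.finite(aics))) {
    err_data("AIC values must be finite")
  }
  w <- exp(-(aics - min(aics)) / 2)
  w / sum(w)
}

#' Fit one model spec to a case-control table
#'
#' @param table A scaled `case_control_table`.
#' @param spec A `model_spec`.
#' @return A `clogit_fit` with the model name attached.
#' @export
fit_model <- function(table, spec) {
  design <- build_design(table, spec$terms)
  fit <- fit_clogit(design)
  fit$model <- spec$name
  fit
}

#' Compete the candidate models per individual
#'
#' Fits every spec to every individual's case-control strata, ranks models
#' by AIC (ties broken toward fewer estimated terms, then name order),
#' computes Akaike weights, and tallies rank-1 and rank-2 finishes per
#' hypothesis. Individuals with any failed or non-converged fit are
#' reported in `$failures` and excluded from the tallies.
#'
#' @param tables A named list of per-individual case-control tables, or one
#'   table carrying several `individual_id`s (split internally).
#' @param specs Named list of `model_spec`s from [build_candidate_set()].
#' @return A `competition_result`: `$table` (one row per individual and
#'   model: aic, delta, weight, loglik, concordance, rank), `$tallies`
#'   (rank-1/rank-2 counts per model), `$fits`, `$failures`.
#' @export
compete <- function(tables, specs) {
  if (is.data.frame(tables)) {
    tables <- split(tables, tables$individual_id)
  }
  rows <- list()
  fits <- list()
  failures <- list()

  for (id in names(tables)) {
    tab <- tables[[id]]
    validate_case_control(tab)
    one <- lapply(specs, function(sp) {
      tryCatch(suppressWarnings(fit_model(tab, sp)),
               error = function(e) e)
    })
    bad <- vapply(one, function(f) {
      inherits(f, "error") || !isTRUE(f$converged)
    }, logical(1))
    if (any(bad)) {
      failures[[id]] <- vapply(one[bad], function(f) {
        if (inherits(f, "error")) conditionMessage(f) else "did not converge"
      }, character(1))
      next
    }
    fits[[id]] <- one
    aic <- vapply(one, `[[`, numeric(1), "aic")
    nterm <- vapply(one, function(f) length(f$beta), numeric(1))
    rank <- order(order(aic, nterm, names(one)))
    rows[[id]] <- data.frame(
      individual_id = id, model = names(one), n_terms = nterm,
      loglik = vapply(one, `[[`, numeric(1), "loglik"),
      aic = aic, delta_aic = aic - min(aic),
      akaike_weight = akaike_weights(aic),
      concordance = vapply(one, `[[`, numeric(1), "concordance"),
      rank = rank, stringsAsFactors = FALSE
    )
  }

  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  model_names <- names(specs)
  tallies <- data.frame(
    model = model_names,
    rank1 = vapply(model_names, function(m) {
      sum(tab$model == m & tab$rank == 1)
    }, numeric(1)),
    rank2 = vapply(model_names, function(m) {
      sum(tab$model == m & tab$rank == 2)
    }, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(table = tab, tallies = tallies, fits = fits,
                 failures = failures),
            class = "competition_result")
}

#' @export
print.competition_result <- function(x, ...) {
  n_id <- length(unique(x$table$individual_id))
  cat(sprintf("<competition_result> %d individual(s), %d excluded\n",
              n_id, length(x$failures)))
  print(x$tallies)
  invisible(x)
}

#' Movement statistics inside protected areas
#'
#' Restricts a step series to steps ending inside a protected area and
#' correlates each movement metric (step length, cosine turn angle) with
#' the forest-class densities at the step end points (Pearson, two-sided t
#' test on n - 2 degrees of freedom).
#'
#' @param steps A `step_series`.
#' @param stack A `landscape_stack`.
#' @param classes Density classes to correlate against (default the forest
#'   classes).
#' @param cov_config A [covariate_config()].
#' @return A `residency_result` data frame: `metric`, `class`, `r`, `df`,
#'   `p`, `n`.
#' @export
pa_residency <- function(steps, stack,
                         classes = c("deciduous", "coniferous", "mixed"),
                         cov_config = covariate_config()) {
  ends <- cbind(steps$end_x, steps$end_y)
  inside <- point_in_mask(stack, ends, stack$pa_mask)
  if (sum(inside) < 3) {
    err_data("fewer than 3 steps end inside a protected area")
  }
  st <- steps[inside, , drop = FALSE]
  pts <- cbind(st$end_x, st$end_y)
  out <- list()
  for (cl in classes) {
    dens <- density_in_buffer(stack, cl, pts, cov_config)
    for (metric in c("step_length", "cos_turn_angle")) {
      v <- if (metric == "step_length") st$length_m else st$cos_turn
      ok <- is.finite(v) & is.finite(dens)
      ct <- suppressWarnings(cor.test(v[ok], dens[ok], method = "pearson"))
      out[[paste(metric, cl)]] <- data.frame(
        metric = metric, class = cl,
        r = unname(ct$estimate), df = unname(ct$parameter),
        p = ct$p.value, n = sum(ok), stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("residency_result", "data.frame")
  res
}

#' Write competition outputs as tidy CSVs
#'
#' @param result A `competition_result`.
#' @param dir Output directory.
#' @export
write_competition_csv <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(result$table, file.path(dir, "competition.csv"),
            row.names = FALSE)
  write.csv(result$tallies, file.path(dir, "tallies.csv"), row.names = FALSE)
  invisible(dir)
}
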