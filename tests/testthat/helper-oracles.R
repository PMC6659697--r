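# Brute-force oracles and small fixtures, independent of the package's
# computational paths.

# exhaustive scan over all cells of the class; same conventions as the
# package (distance to nearest class cell center, 0 on-feature, capped)
bf_distance <- function(stack, class_name, pts, cap = 1000) {
  schema <- stack$schema
  mask <- if (class_name %in% names(stack$linear_masks)) {
    stack$linear_masks[[class_name]]
  } else if (schema$category[schema$class_name == class_name] ==
             "protected_area") {
    stack$pa_mask
  } else {
    stack$cover == match(class_name,
                         schema$class_name[schema$geometry == "polygonal" &
                                             schema$category != "protected_area"])
  }
  nr <- nrow(mask)
  res <- stack$resolution_m
  cells <- which(mask, arr.ind = TRUE)
  vapply(seq_len(nrow(pts)), function(i) {
    x <- pts[i, 1]
    y <- pts[i, 2]
    r0 <- min(max(floor((stack$origin[2] + nr * res - y) / res), 0), nr - 1) + 1
    c0 <- min(max(floor((x - stack$origin[1]) / res), 0), ncol(mask) - 1) + 1
    if (mask[r0, c0]) return(0)
    if (nrow(cells) == 0) return(cap)
    xc <- stack$origin[1] + (cells[, 2] - 0.5) * res
    yc <- stack$origin[2] + (nr - cells[, 1] + 0.5) * res
    min(cap, min(sqrt((x - xc)^2 + (y - yc)^2)))
  }, numeric(1))
}

# exhaustive per-cell scan for buffer density
bf_density <- function(stack, class_name, pts, radius = 106) {
  schema <- stack$schema
  mask <- if (class_name %in% names(stack$linear_masks)) {
    stack$linear_masks[[class_name]]
  } else if (schema$category[schema$class_name == class_name] ==
             "protected_area") {
    stack$pa_mask
  } else {
    stack$cover == match(class_name,
                         schema$class_name[schema$geometry == "polygonal" &
                                             schema$category != "protected_area"])
  }
  nr <- nrow(mask)
  res <- stack$resolution_m
  idx <- expand.grid(r = seq_len(nr), c = seq_len(ncol(mask)))
  xc <- stack$origin[1] + (idx$c - 0.5) * res
  yc <- stack$origin[2] + (nr - idx$r + 0.5) * res
  inmask <- mask[cbind(idx$r, idx$c)]
  vapply(seq_len(nrow(pts)), function(i) {
    d2 <- (pts[i, 1] - xc)^2 + (pts[i, 2] - yc)^2
    inside <- d2 <= radius^2
    sum(inside & inmask) / (sum(inside) * res^2)
  }, numeric(1))
}

# explicit per-stratum softmax evaluation of the partial log-likelihood
bf_partial_loglik <- function(beta, X, stratum, case) {
  ll <- 0
  for (s in unique(stratum)) {
    rows <- which(stratum == s)
    eta <- as.vector(X[rows, , drop = FALSE] %*% beta)
    ll <- ll + eta[case[rows] == 1] - log(sum(exp(eta)))
  }
  ll
}

# explicit double-loop pair counting
bf_concordance <- function(eta, stratum, case) {
  num <- 0
  den <- 0
  for (s in unique(stratum)) {
    rows <- which(stratum == s)
    ec <- eta[rows][case[rows] == 1]
    for (e0 in eta[rows][case[rows] == 0]) {
      den <- den + 1
      if (ec > e0) num <- num + 1 else if (ec == e0) num <- num + 0.5
    }
  }
  num / den
}

# random small landscape built directly from matrices (controlled fixture)
toy_stack <- function(seed = 1, nr = 20, nc = 20, res = 30,
                      n_cover = NULL) {
  schema <- default_feature_schema()
  covers <- schema$class_name[schema$geometry == "polygonal" &
                                schema$category != "protected_area"]
  if (is.null(n_cover)) n_cover <- length(covers)
  withr::with_seed(seed, {
    cover <- matrix(sample.int(n_cover, nr * nc, replace = TRUE), nr, nc)
    pa <- matrix(runif(nr * nc) < 0.2, nr, nc)
    lin <- lapply(c("streams", "rail_lines", "roads"), function(cl) {
      matrix(runif(nr * nc) < 0.05, nr, nc)
    })
    names(lin) <- c("streams", "rail_lines", "roads")
    landscape_stack(cover, pa, lin, resolution_m = res, schema = schema)
  })
}

# data simulated exactly from the conditional logistic model: K+1 candidate
# rows per stratum with N(0,1) covariates, case chosen by softmax(X beta)
sim_clogit_table <- function(beta, n_strata, size = 11, seed = 1) {
  p <- length(beta)
  withr::with_seed(seed, {
    X <- matrix(rnorm(n_strata * size * p), ncol = p)
    colnames(X) <- paste0("x", seq_len(p))
    stratum <- rep(seq_len(n_strata), each = size)
    case <- integer(n_strata * size)
    for (s in seq_len(n_strata)) {
      rows <- which(stratum == s)
      u <- as.vector(X[rows, , drop = FALSE] %*% beta)
      pick <- sample.int(size, 1, prob = exp(u - max(u)))
      case[rows[pick]] <- 1L
    }
    list(X = X, stratum = stratum, case = case)
  })
}

# brute-force maximizer of the partial likelihood for 2-term designs:
# coarse 2-D grid followed by nested 2-D grid refinements
bf_clogit_mle <- function(design, lower = -4, upper = 4) {
  eval_grid <- function(b1s, b2s) {
    g <- as.matrix(expand.grid(b1s, b2s))
    g[which.max(apply(g, 1, partial_loglik, design = design)), ]
  }
  b <- eval_grid(seq(lower, upper, 0.05), seq(lower, upper, 0.05))
  for (hw in c(0.1, 5e-3, 2.5e-4)) {
    step <- hw / 25
    b <- eval_grid(seq(b[1] - hw, b[1] + hw, step),
                   seq(b[2] - hw, b[2] + hw, step))
  }
  unname(b)
}

# small landscape for pipeline-level tests
demo_landscape <- function(seed = 11, extent = c(5100, 5100)) {
  generate_landscape(landscape_config(extent_m = extent, seed = seed))
}
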