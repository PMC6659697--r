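test_that("the candidate set is the five-hypothesis family built on the core", {
  specs <- build_candidate_set()
  expect_length(specs, 5)
  expect_named(specs, c("core", "corridor", "lcp", "stepping_stone", "global"))
  for (sp in specs) expect_true(all(core_terms() %in% sp$terms))
  expect_equal(specs$core$terms, core_terms())
  expect_true("dens_deciduous:lag_dens_deciduous" %in% specs$corridor$terms)
  expect_true("dist_roads:lag_dist_roads" %in% specs$corridor$terms)
  expect_true("dens_mixed:ln_step_length" %in% specs$lcp$terms)
  expect_true(all(c("dist_protected_areas", "dens_protected_areas",
                    "dens_protected_areas:lag_dens_protected_areas") %in%
                    specs$stepping_stone$terms))
  # no lagged main effects anywhere: inestimable under exact conditioning
  mains <- unlist(lapply(specs, function(s) {
    s$terms[!grepl(":", s$terms)]
  }))
  expect_false(any(grepl("^lag_", mains)))

  sc <- default_feature_schema()
  expect_error(build_candidate_set(feature_schema(sc[sc$class_name != "mixed", ])),
               class = "issaconn_schema_error")
})

test_that("the global model drops the later member of a collinear pair", {
  tab <- withr::with_seed(3, {
    n <- 400
    cols <- unique(unlist(strsplit(unlist(lapply(build_candidate_set(),
                                                 `[[`, "terms")), ":")))
    df <- as.data.frame(setNames(lapply(cols, function(x) rnorm(n)), cols))
    df$stratum_id <- rep(1:40, each = 10)
    df
  })
  # inject perfect collinearity: dens_coniferous duplicates dens_deciduous
  tab$dens_coniferous <- tab$dens_deciduous
  specs <- build_candidate_set(table = tab)
  expect_true("dens_deciduous" %in% specs$global$terms)
  expect_false("dens_coniferous" %in% specs$global$terms)
  # untouched without a screen table
  specs0 <- build_candidate_set()
  expect_true("dens_coniferous" %in% specs0$global$terms)
})

test_that("akaike weights follow the closed form", {
  w <- akaike_weights(c(100, 102))
  expect_equal(w, c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(w[1], 0.7311, tolerance = 1e-4)
  expect_equal(akaike_weights(42), 1)
  expect_equal(akaike_weights(rep(7, 4)), rep(0.25, 4))
  expect_equal(sum(akaike_weights(rnorm(6, 100, 10))), 1, tolerance = 1e-12)
  expect_error(akaike_weights(c(1, NA)), class = "issaconn_data_error")
})

test_that("competition ranks, weights and tallies are internally consistent", {
  ls <- demo_landscape(12)
  tabs <- lapply(1:2, function(i) {
    tr <- simulate_track(ls, n_fixes = 500, seed = 30 + i,
                         select = selection_params("corridor"),
                         individual_id = paste0("f", i))
    st <- derive_steps(tr)
    scale_covariates(attach_covariates(
      generate_available(st, fit_step_distribution(st), 10, 40 + i, ls), ls))
  })
  names(tabs) <- c("f1", "f2")
  specs <- build_candidate_set(ls$schema, 0.7, do.call(rbind, tabs))
  comp <- compete(tabs, specs)

  for (id in unique(comp$table$individual_id)) {
    sub <- comp$table[comp$table$individual_id == id, ]
    expect_equal(sum(sub$akaike_weight), 1, tolerance = 1e-12)
    expect_equal(sub$delta_aic[sub$rank == 1], 0)
    expect_equal(which.max(sub$akaike_weight), which(sub$rank == 1))
    expect_setequal(sub$rank, 1:5)
  }
  n_ok <- length(unique(comp$table$individual_id))
  expect_equal(sum(comp$tallies$rank1), n_ok)
  expect_equal(sum(comp$tallies$rank2), n_ok)

  # the corridor model contains every core term, so it can never lose
  # log-likelihood to the core model on the same strata
  specs_all <- build_candidate_set(ls$schema)
  f_core <- fit_model(tabs$f1, specs_all$core)
  f_corr <- suppressWarnings(fit_model(tabs$f1, specs_all$corridor))
  expect_gte(f_corr$loglik, f_core$loglik - 1e-8)
})

test_that("nested specs never lose likelihood: global-with-core-terms vs core", {
  d <- sim_clogit_table(c(0.5, -0.7, 0.2), n_strata = 150, size = 6, seed = 9)
  des_core <- clogit_design(d$X[, 1:2], d$stratum, d$case)
  des_full <- clogit_design(d$X, d$stratum, d$case)
  expect_gte(fit_clogit(des_full)$loglik, fit_clogit(des_core)$loglik - 1e-8)
})

test_that("protected-area residency correlations match direct computation", {
  ls <- toy_stack(21, nr = 35, nc = 35)
  tr <- simulate_track(ls, n_fixes = 400, seed = 3,
                       select = selection_params("null"),
                       start = c(525, 525))
  st <- derive_steps(tr)
  res <- pa_residency(st, ls)
  expect_setequal(unique(res$class), c("deciduous", "coniferous", "mixed"))
  expect_true(all(res$r >= -1 & res$r <= 1))
  expect_true(all(res$df == res$n - 2))

  # oracle: recompute one r as covariance over sd product
  inside <- in_protected_area(ls, cbind(st$end_x, st$end_y))
  sti <- st[inside, ]
  dens <- density_in_buffer(ls, "deciduous", cbind(sti$end_x, sti$end_y))
  r_manual <- cov(sti$length_m, dens) / (sd(sti$length_m) * sd(dens))
  expect_equal(res$r[res$metric == "step_length" &
                       res$class == "deciduous"], r_manual,
               tolerance = 1e-12)

  # self-correlation anchor
  st2 <- sti
  st2$length_m <- dens
  res2 <- pa_residency(st2, ls, classes = "deciduous")
  expect_equal(res2$r[res2$metric == "step_length"], 1, tolerance = 1e-10)

  expect_error(pa_residency(st[1:2, ], ls), class = "issaconn_data_error")
})

test_that("independent metric and density show near-zero residency correlation", {
  ls <- toy_stack(22, nr = 60, nc = 60)
  n <- 8000
  pts <- withr::with_seed(5, cbind(runif(n, 50, 1750), runif(n, 50, 1750)))
  st <- data.frame(
    end_x = pts[, 1], end_y = pts[, 2],
    length_m = withr::with_seed(6, rlnorm(n, 4, 1)),
    cos_turn = withr::with_seed(7, runif(n, -1, 1))
  )
  res <- pa_residency(st, ls, classes = "deciduous")
  expect_true(all(abs(res$r) < 0.05))
  expect_true(all(res$p > 1e-4))
})
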