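mk_track <- function(xy, id = "f1", interval = 300) {
  structure(data.frame(
    individual_id = id,
    timestamp = as.POSIXct("2020-01-01", tz = "UTC") +
      (seq_len(nrow(xy)) - 1) * interval,
    x = xy[, 1], y = xy[, 2], stringsAsFactors = FALSE
  ), class = c("track", "data.frame"))
}

test_that("steps, headings and turns follow the geometry", {
  st <- derive_steps(mk_track(rbind(c(0, 0), c(3, 4), c(6, 8))))
  expect_equal(st$length_m, c(5, 5))
  expect_true(is.na(st$turn_rad[1]))
  expect_equal(st$turn_rad[2], 0)
  expect_equal(st$cos_turn[2], 1)

  st2 <- derive_steps(mk_track(rbind(c(0, 0), c(1, 0), c(1, 1))))
  expect_equal(st2$turn_rad[2], pi / 2)
  expect_equal(st2$cos_turn[2], 0, tolerance = 1e-12)

  expect_error(derive_steps(mk_track(rbind(c(0, 0), c(1, 1)))),
               class = "issaconn_data_error")
})

test_that("turn angles are invariant under rotation of the whole track", {
  xy <- withr::with_seed(8, matrix(cumsum(rnorm(40)), ncol = 2) * 50 + 2000)
  theta <- 0.83
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  a <- derive_steps(mk_track(xy))
  b <- derive_steps(mk_track(xy %*% t(R)))
  expect_equal(a$turn_rad, b$turn_rad, tolerance = 1e-10)
  expect_equal(a$length_m, b$length_m, tolerance = 1e-10)
})

test_that("time gaps split bursts and drop the spanning step", {
  xy <- cbind(seq(0, 900, by = 100), 0)
  tr <- mk_track(xy)
  tr$timestamp[6:10] <- tr$timestamp[6:10] + 3600 # one-hour dropout
  st <- derive_steps(tr)
  expect_equal(nrow(st), 8) # step 5-6 removed
  expect_equal(length(unique(st$burst_id)), 2)
  # first step of the second burst has no turn
  expect_true(is.na(st$turn_rad[st$burst_id == 2][1]))
})

test_that("zero-length steps are dropped with a warning", {
  xy <- rbind(c(0, 0), c(10, 0), c(10, 0), c(20, 0))
  expect_warning(st <- derive_steps(mk_track(xy)), "zero-length")
  expect_equal(nrow(st), 2)
  expect_true(all(st$length_m > 0))
})

test_that("log-normal step distribution fitting recovers and scales correctly", {
  lens <- withr::with_seed(1, rlnorm(5000, 4.2, 0.5))
  st <- data.frame(length_m = lens)
  fit <- fit_step_distribution(st)
  expect_lt(abs(fit$meanlog - 4.2), 0.05)
  expect_lt(abs(fit$sdlog - 0.5), 0.05)

  # scaling all lengths by c shifts meanlog by log(c), leaves sdlog alone
  fit2 <- fit_step_distribution(data.frame(length_m = lens * 3))
  expect_equal(fit2$meanlog, fit$meanlog + log(3), tolerance = 1e-12)
  expect_equal(fit2$sdlog, fit$sdlog, tolerance = 1e-12)

  expect_error(fit_step_distribution(data.frame(length_m = rep(exp(1), 20))),
               class = "issaconn_data_error")
  expect_error(fit_step_distribution(data.frame(length_m = rlnorm(5, 4, 1))),
               class = "issaconn_data_error")
})

test_that("available steps form valid 1:k strata with the declared distributions", {
  ls <- demo_landscape(2)
  tr <- simulate_track(ls, n_fixes = 1200, seed = 5,
                       select = selection_params("null"))
  st <- derive_steps(tr)
  fit <- fit_step_distribution(st)
  tab <- generate_available(st, fit, k = 10, seed = 3, stack = ls)

  sizes <- table(tab$stratum_id)
  expect_true(all(sizes == 11))
  expect_true(all(tapply(tab$case, tab$stratum_id, sum) == 1))
  expect_equal(attr(tab, "k"), 10)

  av <- tab[tab$case == 0, ]
  # available turn angles uniform on (-pi, pi]
  ks <- suppressWarnings(stats::ks.test(av$turn_rad, "punif", -pi, pi))
  expect_gt(ks$p.value, 0.01)
  expect_true(all(av$turn_rad > -pi & av$turn_rad <= pi))
  # available log lengths centered on the fitted meanlog
  se <- fit$sdlog / sqrt(nrow(av))
  expect_lt(abs(mean(av$ln_step_length) - fit$meanlog), 3 * se + 1e-3)
  # determinism
  tab2 <- generate_available(st, fit, k = 10, seed = 3, stack = ls)
  expect_identical(tab, tab2)
  expect_error(generate_available(st, fit, k = 0, seed = 1, stack = ls),
               class = "issaconn_config_error")
})

test_that("covariate attachment matches direct computation and shares lags within strata", {
  ls <- toy_stack(3, nr = 30, nc = 30)
  tr <- simulate_track(ls, n_fixes = 60, seed = 2,
                       select = selection_params("null"),
                       start = c(450, 450))
  st <- derive_steps(tr)
  tab <- generate_available(st, fit_step_distribution(st), k = 5, seed = 7,
                            stack = ls)
  tab <- attach_covariates(tab, ls)

  # lag columns are constant within every stratum
  lag_cols <- grep("^lag_", names(tab), value = TRUE)
  for (cl in lag_cols[c(1, 9, 25)]) {
    spread <- tapply(tab[[cl]], tab$stratum_id, function(v) max(v) - min(v))
    expect_true(all(spread == 0))
  }
  # spot-check one row against density_in_buffer / distance_to directly
  row <- tab[17, ]
  expect_equal(row$dens_wetlands,
               density_in_buffer(ls, "wetlands", cbind(row$end_x, row$end_y)))
  expect_equal(row$dist_streams,
               distance_to(ls, "streams", cbind(row$end_x, row$end_y), 1000))
  # lag covariates are the stratum start point's covariates
  expect_equal(row$lag_dens_mixed,
               density_in_buffer(ls, "mixed", cbind(row$start_x, row$start_y)))
})

test_that("uniform cover makes its density column degenerate after scaling", {
  schema <- default_feature_schema()
  cover <- matrix(match("deciduous", cover_classes(schema)), 40, 40)
  ls <- landscape_stack(cover, schema = schema)
  tr <- simulate_track(ls, n_fixes = 80, seed = 4,
                       select = selection_params("null"))
  st <- derive_steps(tr)
  tab <- attach_covariates(
    generate_available(st, fit_step_distribution(st), 3, 1, ls), ls)
  expect_true(all(tab$dens_deciduous == tab$dens_deciduous[1]))
  out <- scale_covariates(tab)
  expect_true(any(grepl("dens_deciduous", attr(out, "zero_variance"))))
  expect_true(all(out$dens_deciduous == 0))
})
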