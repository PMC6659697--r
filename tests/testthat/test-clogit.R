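test_that("partial log-likelihood matches closed forms and brute force", {
  # beta = 0 with strata of size 11: -S * log(11)
  d <- sim_clogit_table(c(0.5, -1), n_strata = 7, size = 11, seed = 2)
  design <- clogit_design(d$X, d$stratum, d$case)
  expect_equal(partial_loglik(c(0, 0), design), -7 * log(11))
  expect_equal(partial_loglik(c(0, 0),
                              clogit_design(d$X[1:11, ], d$stratum[1:11],
                                            d$case[1:11])),
               -2.397895, tolerance = 1e-6)

  # one stratum, one covariate, x_case = 1, x_control = 0, beta = log 3
  d2 <- clogit_design(matrix(c(1, 0), ncol = 1), c(1, 1), c(1, 0))
  expect_equal(partial_loglik(log(3), d2), log(3 / 4))

  # random small designs match the explicit softmax oracle
  for (seed in 1:5) {
    d3 <- sim_clogit_table(c(0.3, -0.6, 1.1), n_strata = 12, size = 5,
                           seed = seed)
    des <- clogit_design(d3$X, d3$stratum, d3$case)
    beta <- withr::with_seed(seed, rnorm(3))
    expect_equal(partial_loglik(beta, des),
                 bf_partial_loglik(beta, des$X, des$stratum, des$case),
                 tolerance = 1e-10)
  }
  expect_error(partial_loglik(c(0, 0, 0), design),
               class = "issaconn_design_error")
})

test_that("the Newton fit maximizes the partial likelihood (grid-search oracle)", {
  d <- sim_clogit_table(c(0.8, -0.5), n_strata = 3, size = 3, seed = 2)
  des <- clogit_design(d$X, d$stratum, d$case)
  fit <- fit_clogit(des)
  b <- bf_clogit_mle(des)
  expect_lt(max(abs(fit$beta - b)), 1e-4)
  expect_true(fit$converged)
  expect_equal(fit$aic, 2 * 2 - 2 * fit$loglik)
})

test_that("coefficients are recovered within 2 SE in most simulated designs", {
  beta <- c(0.5, -1.0)
  hits <- matrix(FALSE, 40, 2)
  for (r in 1:40) {
    d <- sim_clogit_table(beta, n_strata = 500, size = 11, seed = 1000 + r)
    fit <- fit_clogit(clogit_design(d$X, d$stratum, d$case))
    hits[r, ] <- abs(fit$beta - beta) <= 2 * fit$se
  }
  expect_gte(mean(hits[, 1]), 0.85)
  expect_gte(mean(hits[, 2]), 0.85)
})

test_that("degenerate and invariance properties of the fit hold", {
  d <- sim_clogit_table(c(0.7, -0.4), n_strata = 80, size = 6, seed = 11)
  des <- clogit_design(d$X, d$stratum, d$case)
  fit <- fit_clogit(des)

  # a within-stratum-constant column is dropped, other coefficients intact
  strat_vals <- withr::with_seed(99, rnorm(80))
  Xc <- cbind(d$X, lagged = strat_vals[d$stratum])
  expect_warning(fit2 <- fit_clogit(clogit_design(Xc, d$stratum, d$case)),
                 "within-stratum-constant")
  expect_equal(unname(fit2$beta), unname(fit$beta), tolerance = 1e-10)
  expect_true("lagged" %in% fit2$dropped_terms)

  # rescaling a covariate rescales beta by 1/c; loglik, AIC, concordance fixed
  Xs <- d$X
  Xs[, 1] <- Xs[, 1] * 100
  fit3 <- fit_clogit(clogit_design(Xs, d$stratum, d$case))
  expect_equal(unname(fit3$beta[1]), unname(fit$beta[1]) / 100,
               tolerance = 1e-8)
  expect_equal(fit3$loglik, fit$loglik, tolerance = 1e-8)
  expect_equal(fit3$aic, fit$aic, tolerance = 1e-8)
  expect_equal(fit3$concordance, fit$concordance, tolerance = 1e-10)

  # a duplicated column is dropped as collinear
  Xd <- cbind(d$X, dup = d$X[, 1])
  expect_warning(fit4 <- fit_clogit(clogit_design(Xd, d$stratum, d$case)),
                 "collinear")
  expect_equal(unname(fit4$beta[1:2]), unname(fit$beta), tolerance = 1e-10)

  # nothing estimable -> design error
  Xconst <- matrix(rep(strat_vals[d$stratum], 2), ncol = 2)
  expect_error(suppressWarnings(
    fit_clogit(clogit_design(Xconst, d$stratum, d$case))),
    class = "issaconn_design_error")

  # two case rows in one stratum -> stratum integrity error
  bad_case <- d$case
  bad_case[which(d$stratum == 1 & d$case == 0)[1]] <- 1L
  expect_error(clogit_design(d$X, d$stratum, bad_case),
               "stratum integrity", class = "issaconn_format_error")
})

test_that("concordance matches pair enumeration and its trivial anchors", {
  d <- sim_clogit_table(c(2, 1), n_strata = 30, size = 8, seed = 5)
  des <- clogit_design(d$X, d$stratum, d$case)
  fit <- fit_clogit(des)
  eta <- as.vector(des$X %*% fit$beta)
  expect_equal(stratum_concordance(fit, des),
               bf_concordance(eta, des$stratum, des$case))
  # beta = 0: every pair ties -> 0.5
  fit0 <- fit
  fit0$beta[] <- 0
  expect_equal(stratum_concordance(fit0, des), 0.5)
  # perfect discrimination -> 1
  Xsep <- matrix(as.numeric(d$case), ncol = 1)
  fit1 <- list(terms = "x1", beta = c(x1 = 1))
  expect_equal(stratum_concordance(fit1,
                                   clogit_design(Xsep, d$stratum, d$case)), 1)
})

test_that("optimizers started anywhere agree with Newton (concavity)", {
  d <- sim_clogit_table(c(0.6, -0.9), n_strata = 50, size = 6, seed = 77)
  des <- clogit_design(d$X, d$stratum, d$case)
  fit <- fit_clogit(des)
  for (s in 1:5) {
    start <- withr::with_seed(s, rnorm(2, 0, 2))
    opt <- stats::optim(start, function(b) -partial_loglik(b, des),
                        method = "BFGS",
                        control = list(reltol = 1e-14, maxit = 500))
    expect_lt(max(abs(opt$par - fit$beta)), 1e-5)
  }
})

test_that("the fit agrees with the survival package on random small designs", {
  skip_if_not_installed("survival")
  suppressPackageStartupMessages(library(survival))
  for (seed in 1:20) {
    d <- sim_clogit_table(c(0.6, -0.9), n_strata = 60, size = 6, seed = seed)
    des <- clogit_design(d$X, d$stratum, d$case)
    fit <- fit_clogit(des)
    ref <- survival::clogit(
      case ~ x1 + x2 + strata(stratum),
      data = data.frame(case = d$case, x1 = d$X[, 1], x2 = d$X[, 2],
                        stratum = d$stratum)
    )
    expect_lt(max(abs(fit$beta - coef(ref))), 1e-5)
    expect_equal(fit$loglik, ref$loglik[2], tolerance = 1e-8)
    expect_lt(max(abs(fit$se - sqrt(diag(ref$var)))), 1e-5)
  }
})
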