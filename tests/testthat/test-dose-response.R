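test_that("relative root elongation matches hand-computed means", {
  rre <- compute_rre(toy_root_table())
  # control elongation: mean(50, 60) = 55 mm
  # 10 uM: mean(30, 30) = 30 mm -> 100*30/55
  # 100 uM: zero elongation -> 0
  expect_equal(rre$rre[rre$as_total_uM == 0], 100)
  expect_equal(rre$rre[rre$as_total_uM == 10], 100 * 30 / 55, tolerance = 1e-12)
  expect_equal(rre$rre[rre$as_total_uM == 100], 0)
  expect_equal(rre$n_seeds, rep(2L, 3))

  # treatment elongation equal to control elongation gives RRE = 100
  tbl <- toy_root_table()
  tbl$length_final_mm[3:4] <- tbl$length_initial_mm[3:4] + 55
  expect_equal(compute_rre(tbl)$rre[2], 100, tolerance = 1e-12)

  bad <- toy_root_table()
  bad$length_final_mm[bad$is_control] <- bad$length_initial_mm[bad$is_control]
  expect_error(compute_rre(bad), "control elongation")
  expect_error(compute_rre(toy_root_table()[!toy_root_table()$is_control, ]),
               "no control")
})

test_that("noiseless logistic data are recovered to numerical precision", {
  true <- list(y0 = 8, a = 90, x0 = log(4.5e-5), b = -0.55)
  x <- log(c(0.5, 2, 10, 50, 200, 1000) * 1e-6)
  y <- true$y0 + true$a / (1 + exp(-(x - true$x0) / true$b))
  fit <- fit_dose_response(x, y)
  expect_equal(fit$y0, true$y0, tolerance = 1e-6)
  expect_equal(fit$a, true$a, tolerance = 1e-6)
  expect_equal(fit$x0, true$x0, tolerance = 1e-6)
  expect_equal(fit$b, true$b, tolerance = 1e-6)

  expect_error(fit_dose_response(x, rep(50, 6)), "constant")
  expect_error(fit_dose_response(x[1:4], y[1:4]), "5 distinct")
})

test_that("EC50 extraction solves y = 50 on the fitted curve", {
  x <- log(c(0.5, 2, 10, 50, 200, 1000) * 1e-6)

  # full-range curve: EC50 is exactly exp(x0)
  y <- 100 / (1 + exp(-(x - log(4.5e-5)) / -0.5))
  est <- ec50_from_fit(fit_dose_response(x, y), n_boot = 0)
  expect_equal(est$value, 4.5e-5, tolerance = 1e-6)

  # shifted curve y0 = 10, a = 90: crossing moves off x0; verify against
  # an independent numeric root-finder on the true curve
  y2 <- 10 + 90 / (1 + exp(-(x - log(4.5e-5)) / -0.5))
  est2 <- ec50_from_fit(fit_dose_response(x, y2), n_boot = 0)
  oracle_x <- uniroot(function(xx)
    10 + 90 / (1 + exp(-(xx - log(4.5e-5)) / -0.5)) - 50,
    c(min(x), max(x)), tol = 1e-13)$root
  expect_equal(est2$value, exp(oracle_x), tolerance = 1e-6)
  # closed form of the same crossing: x = x0 - b log(5/4)
  expect_equal(oracle_x, log(4.5e-5) - (-0.5) * log(5 / 4), tolerance = 1e-9)

  # activity rescaling moves EC50 by the same factor
  k <- 10
  est_k <- ec50_from_fit(fit_dose_response(x + log(k), y), n_boot = 0)
  expect_equal(est_k$value, k * est$value, tolerance = 1e-8)

  # a curve pinned above 50% never crosses: error, no silent fallback
  y_hi <- 80 + 15 / (1 + exp(-(x - log(4.5e-5)) / -0.5))
  expect_error(ec50_from_fit(fit_dose_response(x, y_hi), n_boot = 0),
               "cross 50")
})

test_that("bootstrap EC50 uncertainty is reproducible and shrinks with data", {
  set.seed(11)
  x6 <- log(c(0.5, 2, 10, 50, 200, 1000) * 1e-6)
  mu <- 100 / (1 + exp(-(x6 - log(4.5e-5)) / -0.5))
  y6 <- mu + rnorm(6, 0, 3)
  fit6 <- fit_dose_response(x6, y6)
  e1 <- ec50_from_fit(fit6, n_boot = 400)
  e2 <- ec50_from_fit(fit6, n_boot = 400)
  expect_identical(e1$sd, e2$sd)   # fixed internal seed

  # replicating every dose tightens the parameter covariance
  x12 <- rep(x6, 2)
  y12 <- rep(mu, 2) + rnorm(12, 0, 3)
  e12 <- ec50_from_fit(fit_dose_response(x12, y12), n_boot = 400)
  expect_lt(e12$sd, 2 * e1$sd)   # allow noise, but no blow-up
  expect_gt(e1$sd, 0)
})

test_that("noisy simulated assays recover EC50 within the bootstrap CI", {
  x <- log(c(0.5, 2, 10, 50, 200, 1000) * 1e-6)
  true_ec50 <- 4.5e-5
  mu <- 100 / (1 + exp(-(x - log(true_ec50)) / -0.5))
  n_cover <- 0
  n_run <- 0
  set.seed(99)
  for (s in 1:200) {
    # per-treatment mean of 6 seeds at 5% per-seed RRE noise
    y <- mu + rnorm(6, 0, 5 / sqrt(6))
    est <- tryCatch(
      ec50_from_fit(fit_dose_response(x, y), n_boot = 200),
      error = function(e) NULL)
    if (is.null(est) || is.na(est$sd)) next
    n_run <- n_run + 1
    # 6 points minus 4 parameters: 2 residual df, so the 95% interval
    # uses the t quantile, not the normal one
    tq <- qt(0.975, df = 2)
    ci <- est$value + c(-tq, tq) * est$sd
    if (true_ec50 >= ci[1] && true_ec50 <= ci[2]) n_cover <- n_cover + 1
  }
  expect_gt(n_run, 180)
  expect_gte(n_cover / n_run, 0.9)
})
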