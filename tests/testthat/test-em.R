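test_that("truncated Lindley mean matches quadrature and its limits", {
  expect_equal(etrunc_lindley(1, 1), 1 + 4 / 3, tolerance = 1e-12)
  for (y in c(0.1, 1, 5, 40)) {
    for (th in c(0.05, 0.5, 1, 3)) {
      expect_equal(etrunc_lindley(y, th), etrunc_quadrature(y, th),
                   tolerance = 1e-8)
      expect_gt(etrunc_lindley(y, th), y)
    }
  }
  # y -> 0 recovers the unconditional mean (theta + 2)/(theta (theta + 1))
  th <- 0.7
  expect_equal(etrunc_lindley(1e-12, th), (th + 2) / (th * (th + 1)),
               tolerance = 1e-9)
  expect_error(etrunc_lindley(-1, 1), "positive")
})

test_that("working mean reduces to the sample mean at the last stage and exceeds it otherwise", {
  y <- c(10, 20, 35)
  expect_equal(em_wbar(0.05, j = 4, J = 5, y = y), mean(y), tolerance = 1e-12)
  for (j in 0:3) expect_gt(em_wbar(0.05, j, J = 5, y = y), mean(y))

  # closed form agrees with the term-by-term quadrature assembly
  y0 <- table1_printed()[1, ]
  th <- 0.00837
  wbar_quad <- mean(y0 + (4 / 5) *
                      (vapply(y0, etrunc_quadrature, numeric(1), theta = th) - y0))
  expect_equal(em_wbar(th, 0, 5, y0), wbar_quad, tolerance = 1e-8)
  # frozen quadrature value for that stage and parameter
  expect_equal(em_wbar(th, 0, 5, y0), 237.9374991741, tolerance = 1e-9)

  # algebraic identity with the printed fractional form
  wbar_printed <- mean(y0 + (4 / 5) * (th + th * y0 + 2) /
                         (th * (th + th * y0 + 1)))
  expect_equal(em_wbar(th, 0, 5, y0), wbar_printed, tolerance = 1e-13)
  expect_error(em_wbar(1, j = 5, J = 5, y = y), "surviving component")
})

test_that("M-step root solves the score equation exactly", {
  expect_equal(em_mstep(1), sqrt(2), tolerance = 1e-14)
  for (w in c(0.1, 1, 34.84)) {
    th <- em_mstep(w)
    expect_equal(2 / th - 1 / (th + 1) - w, 0, tolerance = 1e-12)
  }
  # monotone decreasing, ~ 2/w for large w
  ws <- c(1, 10, 100, 1000)
  ths <- vapply(ws, em_mstep, numeric(1))
  expect_true(all(diff(ths) < 0))
  expect_equal(em_mstep(1e6) * 1e6 / 2, 1, tolerance = 1e-3)
  expect_error(em_mstep(0), "positive")
})

test_that("per-stage EM reproduces the printed estimates from any start and ascends", {
  gaps <- t(table1_printed())
  printed <- c(0.00837, 0.01994, 0.03099, 0.03908, 0.05589)
  for (th0 in c(1e-3, 0.5, 0.99)) {
    tr <- em_fit_stage(gaps[, 1], j = 0, J = 5, theta0 = th0)
    expect_true(tr$converged)
    expect_equal(round(tr$theta, 5), 0.00837)
  }
  for (j in 0:4) {
    tr <- em_fit_stage(gaps[, j + 1], j, J = 5, theta0 = 0.37)
    expect_equal(round(tr$theta, 5), printed[j + 1])
    # ascent: observed stage log-likelihood never decreases
    expect_true(all(diff(tr$logliks) >= -1e-10))
  }
  # last stage: the working mean is constant, one M-step suffices
  tr4 <- em_fit_stage(gaps[, 5], j = 4, J = 5, theta0 = 0.9)
  expect_equal(tr4$theta, mle_lindley(gaps[, 5]), tolerance = 1e-12)
  expect_lte(tr4$iterations, 2L)
})

test_that("EM fixed point is the unique stage maximiser", {
  d <- table1_gaps()
  gaps <- unclass(d)
  fit <- em_fit(d)
  for (j in 0:4) {
    th_hat <- fit$estimates[j + 1]
    # oracle: dense-grid + Brent maximisation of the stage objective
    oracle <- stage_oracle_maximiser(gaps[, j + 1], j, 5,
                                     lower = th_hat / 50, upper = th_hat * 50)
    expect_equal(th_hat, oracle, tolerance = 1e-6)
    # stationarity by central differences
    h <- th_hat * 1e-5
    deriv <- (stage_loglik(th_hat + h, j, d) -
                stage_loglik(th_hat - h, j, d)) / (2 * h)
    expect_lt(abs(deriv), 1e-4)
  }
})

test_that("full EM fit reproduces the printed analysis and is exchangeable", {
  d <- table1_gaps()
  fit <- em_fit(d)
  expect_true(fit$converged)
  expect_equal(round(fit$estimates, 5),
               c(0.00837, 0.01994, 0.03099, 0.03908, 0.05589))
  expect_equal(fit$loglik, -223.63, tolerance = 0.005)
  expect_equal(fit$loglik, loadshare_loglik(fit$estimates, d),
               tolerance = 1e-12)

  set.seed(8)
  d_perm <- loadshare(unclass(d)[sample(10), ])
  expect_equal(em_fit(d_perm)$estimates, fit$estimates, tolerance = 1e-10)
  expect_error(em_fit(d, theta0 = c(1, 2)), "length J")
})

test_that("EM ascends the full likelihood and is stationary on simulated data", {
  for (rep in 1:5) {
    d <- simulate_loadshare(15, thetas = c(0.02, 0.05, 0.2), seed = 900 + rep)
    fit <- em_fit(d, theta0 = rep(0.5, 3))
    for (tr in fit$traces) {
      expect_true(all(diff(tr$logliks) >= -1e-10))
      h <- tr$theta * 1e-5
      deriv <- (stage_loglik(tr$theta + h, tr$j, d) -
                  stage_loglik(tr$theta - h, tr$j, d)) / (2 * h)
      # derivative scaled to a unit-curvature neighbourhood
      expect_lt(abs(deriv) * tr$theta^2, 1e-4)
    }
  }
})
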