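test_that("density matches its closed form and integrates to one", {
  # hand values
  expect_equal(dlindley(0, 3), 9 / 4)
  expect_equal(dlindley(1, 2), (8 / 3) * exp(-2), tolerance = 1e-12)
  # log variant agrees with the natural scale
  xs <- c(0.01, 0.5, 1, 7, 40)
  for (th in c(0.01, 0.5, 1, 5)) {
    expect_equal(dlindley(xs, th, log = TRUE), log(dlindley(xs, th)),
                 tolerance = 1e-12)
    expect_equal(integrate(dlindley, 0, Inf, theta = th,
                           rel.tol = 1e-10)$value, 1, tolerance = 1e-8)
  }
  expect_error(dlindley(-1, 1), "non-negative")
  expect_error(dlindley(1, -1), "positive")
  expect_error(dlindley(1, 0), "positive")
})

test_that("distribution function matches quadrature of the density", {
  expect_equal(plindley(0, 2), 0)
  expect_equal(slindley(0, 2), 1)
  expect_equal(plindley(1, 1), 1 - 1.5 * exp(-1), tolerance = 1e-12)
  for (th in c(0.05, 1, 3)) {
    for (x in c(0.1, 1, 5, 20)) {
      expect_equal(plindley(x, th),
                   integrate(dlindley, 0, x, theta = th,
                             rel.tol = 1e-12)$value,
                   tolerance = 1e-10)
    }
  }
  # cdf nondecreasing, survival complements
  xs <- seq(0, 30, length.out = 200)
  p <- plindley(xs, 0.4)
  expect_true(all(diff(p) >= 0))
  expect_equal(p + slindley(xs, 0.4), rep(1, length(xs)), tolerance = 1e-12)
})

test_that("hazard equals pdf/survival, increases, and saturates at theta", {
  expect_equal(hlindley(0, 2), 4 / 3)
  expect_equal(hlindley(2, 1), dlindley(2, 1) / slindley(2, 1),
               tolerance = 1e-12)
  for (th in c(0.1, 1, 4)) {
    xs <- seq(0, 200, length.out = 500)
    h <- hlindley(xs, th)
    expect_true(all(diff(h) > 0))
    expect_true(all(h < th))
    expect_equal(hlindley(1e6, th), th, tolerance = 1e-5)
  }
})

test_that("quantile function inverts the cdf", {
  expect_identical(qlindley(0, 1), 0)
  # frozen bisection value for the Lindley(1) median
  expect_equal(qlindley(0.5, 1), 1.146193, tolerance = 1e-6)
  for (th in c(0.05, 1, 3)) {
    for (x in c(0.1, 1, 10)) {
      # deep in the upper tail 1 - F(x) falls below double precision
      # relative to 1, so the round trip is representability-limited
      sv <- slindley(x, th)
      tol <- max(1e-8, 2 * .Machine$double.eps / sv / th / x)
      expect_equal(qlindley(plindley(x, th), th), x, tolerance = tol)
    }
    ps <- c(0, 1e-12, 0.1, 0.5, 0.9, 0.999, 1 - 1e-9)
    expect_equal(plindley(qlindley(ps, th), th), ps, tolerance = 1e-8)
  }
  expect_error(qlindley(1, 1), "\\[0, 1\\)")
  expect_error(qlindley(-0.1, 1), "\\[0, 1\\)")
})

test_that("random generation is inverse-CDF, reproducible, and Lindley", {
  set.seed(11)
  x1 <- rlindley(100, 2)
  set.seed(11)
  x2 <- rlindley(100, 2)
  expect_identical(x1, x2)
  expect_true(all(x1 > 0))

  # mean identity (theta + 2) / (theta (theta + 1)) at theta = 1
  set.seed(101)
  x <- rlindley(1e5, 1)
  expect_equal(mean(x), 1.5, tolerance = 0.02)

  # one-sample KS against the cdf
  set.seed(202)
  ks1 <- suppressWarnings(ks.test(rlindley(1e4, 0.7), plindley, theta = 0.7))
  expect_gt(ks1$p.value, 0.01)

  # two-sample KS against the exponential/gamma mixture representation
  set.seed(303)
  ks2 <- suppressWarnings(ks.test(rlindley(1e4, 0.7),
                                  rlindley_mixture(1e4, 0.7)))
  expect_gt(ks2$p.value, 0.01)
  expect_error(rlindley(0, 1), "positive count")
})

test_that("closed-form one-sample MLE solves the score equation and wins a grid search", {
  # exact roots
  expect_equal(mle_lindley(rep(1, 4)), sqrt(2), tolerance = 1e-12)
  expect_equal(mle_lindley(rep(2, 4)), (-1 + sqrt(17)) / 4, tolerance = 1e-12)
  # printed last-stage row: mean 34.840
  y4 <- table1_printed()[5, ]
  expect_equal(mean(y4), 34.840, tolerance = 1e-12)
  expect_equal(round(mle_lindley(y4), 5), 0.05589)
  # score equation 2/theta - 1/(theta + 1) = ybar
  for (ybar in c(0.1, 1, 34.84)) {
    th <- mle_lindley(rep(ybar, 3))
    expect_equal(2 / th - 1 / (th + 1), ybar, tolerance = 1e-12)
  }
  # maximality: dense grid around the estimate never beats it
  set.seed(5)
  y <- rlindley(40, 0.8)
  th_hat <- mle_lindley(y)
  ll <- function(th) sum(dlindley(y, th, log = TRUE))
  grid <- seq(th_hat / 10, th_hat * 10, length.out = 2000)
  expect_true(max(vapply(grid, ll, numeric(1))) <= ll(th_hat) + 1e-9)
  expect_error(mle_lindley(numeric(0)), "nonempty")
  expect_error(mle_lindley(c(1, -2)), "positive")
})
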