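# Independent oracles used across the suite. These stay deliberately
# naive (quadrature, mixtures, direct transcription) so they never share
# code with the implementation paths they check.

# the printed 10 x 5 gap-time table, built in code, stages-as-rows
table1_printed <- function() {
  rbind(
    c(83.10, 74.91, 164.79, 60.12, 81.91, 132.68, 16.36, 54.71, 130.95, 39.10),
    c(59.25, 53.01, 60.31, 46.38, 20.69, 25.53, 56.11, 28.99, 23.04, 32.21),
    c(30.13, 12.06, 32.91, 47.96, 21.64, 4.80, 19.79, 17.11, 49.43, 66.28),
    c(47.29, 10.45, 6.43, 17.80, 67.01, 37.41, 41.89, 20.17, 21.62, 41.60),
    c(46.24, 39.60, 17.67, 18.72, 50.69, 29.66, 14.16, 52.53, 10.02, 69.11))
}

# Lindley sampler as an exponential/gamma mixture: Exp(theta) with
# probability theta/(theta+1), else Gamma(shape 2, rate theta). Used
# only as a distributional oracle against the inverse-CDF sampler.
rlindley_mixture <- function(n, theta) {
  pick_exp <- stats::runif(n) < theta / (theta + 1)
  ifelse(pick_exp,
         stats::rexp(n, rate = theta),
         stats::rgamma(n, shape = 2, rate = theta))
}

# mean of a Lindley(theta) truncated to (y, Inf), by quadrature of the
# truncated density f(z) / S(y)
etrunc_quadrature <- function(y, theta) {
  dens <- function(z) {
    theta^2 / (theta + theta * y + 1) * (1 + z) * exp(-theta * (z - y))
  }
  stats::integrate(function(z) z * dens(z), y, Inf, rel.tol = 1e-12)$value
}

# direct transcription of the proportional ("constant-dropped")
# log-likelihood expression: per-stage terms without n * log(J - j)
loglik_propto <- function(theta, gaps) {
  n <- nrow(gaps)
  J <- ncol(gaps)
  total <- 0
  for (col in seq_len(J)) {
    j <- col - 1L
    k <- J - j
    y <- gaps[, col]
    th <- theta[col]
    total <- total + 2 * n * log(th) + sum(log(1 + y)) +
      (k - 1) * sum(log(th + 1 + th * y)) -
      n * k * log(th + 1) - k * th * sum(y)
  }
  total
}

# dense grid + Brent refinement maximiser of a 1-D stage log-likelihood
stage_oracle_maximiser <- function(y, j, J, lower, upper) {
  grid <- exp(seq(log(lower), log(upper), length.out = 400))
  ll <- vapply(grid, function(th) sum(dstage(y, j, J, th, log = TRUE)),
               numeric(1))
  centre <- grid[which.max(ll)]
  stats::optimize(function(th) sum(dstage(y, j, J, th, log = TRUE)),
                  interval = c(centre / 3, centre * 3),
                  maximum = TRUE, tol = 1e-12)$maximum
}
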