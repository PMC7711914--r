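#' The Lindley distribution
#'
#' Density, distribution function, survival function, hazard function,
#' quantile function and random generation for the Lindley distribution
#' with rate-like parameter `theta` (inverse time units).
#'
#' The Lindley density is
#' \deqn{f(x) = \frac{\theta^2 (1 + x) e^{-\theta x}}{\theta + 1}, \quad x \ge 0,}
#' a mixture of an exponential and a gamma component with a strictly
#' increasing hazard \eqn{h(x) = \theta^2 (1+x) / (\theta + 1 + \theta x)}
#' that approaches \eqn{\theta} from below. Its mean is
#' \eqn{(\theta + 2) / (\theta(\theta + 1))}.
#'
#' The quantile function inverts
#' \eqn{F(x) = 1 - (\theta + 1 + \theta x) e^{-\theta x} / (\theta + 1)}
#' in closed form through the \eqn{-1} branch of the Lambert W function,
#' \deqn{Q(p) = -1 - \frac{1}{\theta} -
#'   \frac{1}{\theta} W_{-1}\!\left(-(\theta+1)(1-p)\,e^{-(\theta+1)}\right),}
#' with a guarded bisection fallback when the argument sits within
#' `1e-12` of the branch point \eqn{-1/e}. Random generation is by
#' inversion of uniforms, so draws are reproducible under [set.seed()].
#'
#' @param x,q vector of non-negative quantiles.
#' @param p vector of probabilities in `[0, 1)`.
#' @param n number of draws.
#' @param theta positive rate-like parameter.
#' @param log,log.p logical; if `TRUE`, probabilities/densities are
#'   returned on the log scale.
#' @param lower.tail logical; if `TRUE` (default) probabilities are
#'   \eqn{P(X \le x)}, otherwise \eqn{P(X > x)}.
#'
#' @return `dlindley` gives the density, `plindley` the distribution
#'   function, `slindley` the survival function, `hlindley` the hazard,
#'   `qlindley` the quantile function and `rlindley` generates random
#'   deviates.
#'
#' @examples
#' dlindley(1, theta = 2)          # (8/3) * exp(-2)
#' plindley(1, theta = 1)          # 1 - 1.5 * exp(-1)
#' qlindley(plindley(2, 0.7), 0.7) # round trip -> 2
#' set.seed(1); mean(rlindley(1e4, 1)) # ~ (1 + 2) / (1 * 2) = 1.5
#' @name lindley
NULL

check_theta <- function(theta) {
  if (!is.numeric(theta) || any(!is.finite(theta)) || any(theta <= 0))
    stop("'theta' must be positive and finite", call. = FALSE)
  invisible(theta)
}

#' @rdname lindley
#' @export
dlindley <- function(x, theta, log = FALSE) {
  check_theta(theta)
  if (any(x < 0, na.rm = TRUE))
    stop("'x' must be non-negative", call. = FALSE)
  ld <- 2 * base::log(theta) + log1p(x) - theta * x - log1p(theta)
  if (log) ld else exp(ld)
}

#' @rdname lindley
#' @export
plindley <- function(q, theta, lower.tail = TRUE, log.p = FALSE) {
  check_theta(theta)
  if (any(q < 0, na.rm = TRUE))
    stop("'q' must be non-negative", call. = FALSE)
  # log S(q) = log(theta + 1 + theta q) - theta q - log(theta + 1)
  ls <- base::log(theta + 1 + theta * q) - theta * q - log1p(theta)
  if (!lower.tail) {
    if (log.p) ls else exp(ls)
  } else {
    p <- -expm1(ls)
    if (log.p) base::log(p) else p
  }
}

#' @rdname lindley
#' @export
slindley <- function(q, theta, log.p = FALSE) {
  plindley(q, theta, lower.tail = FALSE, log.p = log.p)
}

#' @rdname lindley
#' @export
hlindley <- function(x, theta, log = FALSE) {
  check_theta(theta)
  if (any(x < 0, na.rm = TRUE))
    stop("'x' must be non-negative", call. = FALSE)
  lh <- 2 * base::log(theta) + log1p(x) - base::log(theta + 1 + theta * x)
  if (log) lh else exp(lh)
}

#' @rdname lindley
#' @export
qlindley <- function(p, theta) {
  check_theta(theta)
  if (any(!is.finite(p)) || any(p < 0) || any(p >= 1))
    stop("'p' must lie in [0, 1)", call. = FALSE)
  a <- -(theta + 1) * (1 - p) * exp(-(theta + 1))
  out <- numeric(length(a))
  # branch point of W_{-1} is -exp(-1); fall back to bisection nearby
  near <- a < -exp(-1) + 1e-12
  if (any(!near)) {
    w <- vapply(a[!near], pracma::lambertWn, numeric(1))
    th <- if (length(theta) == 1L) theta else theta[!near]
    out[!near] <- -1 - 1 / th - w / th
  }
  if (any(near)) {
    th <- if (length(theta) == 1L) rep(theta, length(a)) else theta
    out[near] <- mapply(function(pp, tt) {
      if (pp == 0) return(0)
      stats::uniroot(function(x) plindley(x, tt) - pp,
                     lower = 0, upper = 1e3 / tt, tol = 1e-12,
                     extendInt = "upX")$root
    }, p[near], th[near])
  }
  out <- pmax(out, 0)
  # one Newton polish on log S(x) = log(1 - p); d log S / dx = -hazard
  pos <- p > 0
  if (any(pos)) {
    tgt <- log1p(-p[pos])
    xp <- out[pos]
    thp <- if (length(theta) == 1L) theta else theta[pos]
    xp <- xp + (plindley(xp, thp, lower.tail = FALSE, log.p = TRUE) - tgt) /
      hlindley(xp, thp)
    out[pos] <- pmax(xp, 0)
  }
  out
}

#' @rdname lindley
#' @export
rlindley <- function(n, theta) {
  if (length(n) != 1L || !is.finite(n) || n < 1)
    stop("'n' must be a positive count", call. = FALSE)
  check_theta(theta)
  qlindley(stats::runif(n), theta)
}

#' Closed-form maximum-likelihood estimate for a Lindley sample
#'
#' For an i.i.d. Lindley sample the score equation
#' \eqn{2/\theta - 1/(\theta + 1) = \bar y} has the unique positive root
#' \deqn{\hat\theta = \frac{-(\bar y - 1) + \sqrt{(\bar y - 1)^2 + 8 \bar y}}
#'   {2 \bar y},}
#' which is the maximum-likelihood estimate. The same root, applied to
#' the EM working mean instead of the sample mean, is the M-step of
#' [em_fit_stage()].
#'
#' @param x vector of positive observations.
#' @return the scalar estimate \eqn{\hat\theta}.
#' @seealso [em_mstep()] for the same root applied to an EM working mean.
#' @examples
#' mle_lindley(c(1, 2, 3))
#' abs(mle_lindley(rep(1, 5)) - sqrt(2)) < 1e-12
#' @export
mle_lindley <- function(x) {
  if (length(x) == 0 || any(!is.finite(x)) || any(x <= 0))
    stop("'x' must be a nonempty vector of positive values", call. = FALSE)
  em_mstep(mean(x))
}
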