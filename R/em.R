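#' EM building blocks: truncated mean, working mean, M-step
#'
#' The E-step treats each stage-`j` gap as a completely masked competing
#' risk among the `J - j` survivors: the failed component contributes its
#' observed lifetime `y` (it caused the failure with masking probability
#' `1/(J - j)`), while each of the other `J - j - 1` survivors
#' contributes a latent residual lifetime censored at `y`, replaced by
#' its conditional expectation under the current parameter.
#'
#' `etrunc_lindley(y, theta)` is that conditional expectation: the mean
#' of a Lindley(`theta`) variable truncated to `(y, Inf)`,
#' \deqn{E[Z \mid Z > y] = y +
#'   \frac{\theta + \theta y + 2}{\theta(\theta + \theta y + 1)},}
#' which tends to the unconditional Lindley mean
#' \eqn{(\theta + 2)/(\theta(\theta + 1))} as `y -> 0` and always
#' exceeds `y`.
#'
#' `em_wbar` assembles the stage working mean
#' \deqn{\bar w = \frac{1}{n} \sum_i \left[ y_i +
#'   \frac{J - j - 1}{J - j}\,(E[Z_i \mid Z_i > y_i] - y_i) \right],}
#' the expected complete-data mean lifetime per component. For the last
#' stage (`J - j = 1`) the censored term vanishes and `em_wbar` is the
#' plain sample mean.
#'
#' `em_mstep` maximises the expected complete-data log-likelihood, whose
#' first-order condition is the score equation
#' \eqn{2/\theta - 1/(\theta + 1) = \bar w}, solved in closed form by
#' \deqn{\theta' = \frac{-(\bar w - 1) + \sqrt{(\bar w - 1)^2 + 8\bar w}}
#'   {2 \bar w}.}
#'
#' @param y positive gap time(s).
#' @param theta current positive parameter value.
#' @param j stage index (from 0); `J` component count.
#' @param J number of components.
#' @param wbar positive working mean.
#' @return `etrunc_lindley`: the truncated mean(s); `em_wbar`: the scalar
#'   working mean; `em_mstep`: the updated parameter.
#' @examples
#' etrunc_lindley(1, 1)            # 1 + 4/3
#' em_mstep(1)                      # sqrt(2)
#' em_wbar(0.05, j = 4, J = 5, y = c(10, 20))  # == mean(c(10, 20))
#' @name em_steps
NULL

#' @rdname em_steps
#' @export
etrunc_lindley <- function(y, theta) {
  check_theta(theta)
  if (any(y <= 0))
    stop("'y' must be strictly positive", call. = FALSE)
  y + (theta + theta * y + 2) / (theta * (theta + theta * y + 1))
}

#' @rdname em_steps
#' @export
em_wbar <- function(theta, j, J, y) {
  if (J - j < 1)
    stop("need at least one surviving component (j <= J - 1)", call. = FALSE)
  if (length(y) == 0)
    stop("empty stage sample", call. = FALSE)
  k <- J - j
  mean(y + ((k - 1) / k) * (etrunc_lindley(y, theta) - y))
}

#' @rdname em_steps
#' @export
em_mstep <- function(wbar) {
  if (!is.finite(wbar) || wbar <= 0)
    stop("'wbar' must be positive", call. = FALSE)
  (-(wbar - 1) + sqrt((wbar - 1)^2 + 8 * wbar)) / (2 * wbar)
}

#' Fit one load-sharing stage by the EM algorithm
#'
#' Iterates `theta <- em_mstep(em_wbar(theta, j, J, y))` from `theta0`
#' until the relative change in `theta` drops below `tol` or `max_iter`
#' is reached. Each iterate's observed stage log-likelihood is recorded;
#' by the EM ascent property the recorded sequence is nondecreasing.
#' Because the working mean is a smooth contraction toward the unique
#' stationary point of the (unimodal) stage likelihood, the iteration is
#' insensitive to the starting value.
#'
#' @param y positive stage gap times (one per system).
#' @param j stage index from 0; `J` component count.
#' @param J number of components.
#' @param theta0 positive starting value; defaults to `1/mean(y)`
#'   (scale-aware; the answer does not depend on it).
#' @param tol relative-change stopping threshold.
#' @param max_iter iteration cap; hitting it flags `converged = FALSE`
#'   rather than raising an error.
#' @return a list of class `em_trace`: `theta` (final estimate), `j`,
#'   `iterates` (including the start), `logliks` (observed stage
#'   log-likelihood at each iterate beyond the start), `iterations`,
#'   `converged`.
#' @examples
#' d <- table1_gaps()
#' tr <- em_fit_stage(unclass(d)[, 1], j = 0, J = 5)
#' round(tr$theta, 5)
#' @export
em_fit_stage <- function(y, j, J, theta0 = NULL, tol = 1e-10,
                         max_iter = 10000L) {
  if (any(!is.finite(y)) || any(y <= 0))
    stop("stage gaps must be positive and finite", call. = FALSE)
  if (is.null(theta0)) theta0 <- 1 / mean(y)
  check_theta(theta0)
  stage_ll <- function(th) sum(dstage(y, j, J, th, log = TRUE))
  iterates <- theta <- theta0
  logliks <- numeric(0)
  converged <- FALSE
  s <- 0L
  while (s < max_iter) {
    s <- s + 1L
    theta_new <- em_mstep(em_wbar(theta, j, J, y))
    iterates <- c(iterates, theta_new)
    logliks <- c(logliks, stage_ll(theta_new))
    if (abs(theta_new - theta) / theta < tol) {
      theta <- theta_new
      converged <- TRUE
      break
    }
    theta <- theta_new
  }
  structure(list(theta = theta, j = j, J = J, iterates = iterates,
                 logliks = logliks, iterations = s, converged = converged),
            class = "em_trace")
}

#' Maximum-likelihood fit of the load-sharing model by EM
#'
#' The observed likelihood factorises over stages, so the J-dimensional
#' problem splits into J independent one-dimensional EM iterations, one
#' per stage ([em_fit_stage()]). This factorisation is the structural
#' reason the EM estimator cannot wander between local optima the way a
#' joint Newton iteration can: each stage objective is unimodal and its
#' EM map has a single fixed point.
#'
#' @param data a [loadshare] object.
#' @param theta0 optional vector of `J` positive starting values;
#'   defaults to `1/colMeans(gaps)` per stage.
#' @param tol,max_iter per-stage stopping rule, see [em_fit_stage()].
#' @return an object of class `loadshare_fit` with fields `method`
#'   (`"em"`), `estimates` (length-J vector), `loglik` (full observed
#'   log-likelihood at the estimates), `traces` (list of `em_trace`),
#'   `converged`.
#' @examples
#' fit <- em_fit(table1_gaps())
#' round(fit$estimates, 5)
#' round(fit$loglik, 2)
#' @export
em_fit <- function(data, theta0 = NULL, tol = 1e-10, max_iter = 10000L) {
  stopifnot(is_loadshare(data))
  J <- n_components(data)
  m <- gaps_matrix(data)
  if (!is.null(theta0)) {
    if (length(theta0) != J)
      stop(sprintf("'theta0' must have length J = %d", J), call. = FALSE)
    check_theta(theta0)
  }
  traces <- lapply(seq_len(J) - 1L, function(j) {
    em_fit_stage(m[, j + 1L], j, J,
                 theta0 = if (is.null(theta0)) NULL else theta0[j + 1L],
                 tol = tol, max_iter = max_iter)
  })
  est <- vapply(traces, `[[`, numeric(1), "theta")
  structure(list(method = "em",
                 estimates = est,
                 loglik = loadshare_loglik(est, data),
                 traces = traces,
                 iterations = vapply(traces, `[[`, integer(1), "iterations"),
                 converged = all(vapply(traces, `[[`, logical(1), "converged"))),
            class = "loadshare_fit")
}

#' @export
print.loadshare_fit <- function(x, digits = 5, ...) {
  cat(sprintf("Load-sharing fit (%s)\n", toupper(x$method)))
  est <- round(x$estimates, digits)
  names(est) <- paste0("theta_", seq_along(est) - 1L)
  print(est)
  cat(sprintf("log-likelihood: %.4f   converged: %s\n",
              x$loglik, x$converged))
  invisible(x)
}
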