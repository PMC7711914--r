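#' Score and Hessian of the load-sharing log-likelihood
#'
#' Analytic gradient and Hessian of [loadshare_loglik()] with respect to
#' the stage parameters. The log-likelihood is a sum of per-stage terms,
#' each in its own parameter, so the Hessian is diagonal by construction.
#' The stage-`j` gradient component is
#' \deqn{\frac{\partial \ell}{\partial \theta} = \frac{2n}{\theta}
#'   + (J - j - 1) \sum_i \frac{1 + y_i}{\theta + 1 + \theta y_i}
#'   - \frac{n (J - j)}{\theta + 1} - (J - j) \sum_i y_i.}
#'
#' @param theta numeric vector of `J` positive stage parameters.
#' @param data a [loadshare] object.
#' @return `loadshare_score`: length-`J` gradient vector;
#'   `loadshare_hessian`: diagonal `J x J` Hessian matrix.
#' @examples
#' d <- table1_gaps()
#' loadshare_score(em_fit(d)$estimates, d)  # ~ 0 at the MLE
#' @export
loadshare_score <- function(theta, data) {
  stopifnot(is_loadshare(data))
  J <- n_components(data)
  if (length(theta) != J)
    stop(sprintf("'theta' must have length J = %d", J), call. = FALSE)
  check_theta(theta)
  n <- n_systems(data)
  m <- gaps_matrix(data)
  vapply(seq_len(J), function(col) {
    j <- col - 1L
    k <- J - j
    y <- m[, col]
    th <- theta[col]
    2 * n / th + (k - 1) * sum((1 + y) / (th + 1 + th * y)) -
      n * k / (th + 1) - k * sum(y)
  }, numeric(1))
}

#' @rdname loadshare_score
#' @export
loadshare_hessian <- function(theta, data) {
  stopifnot(is_loadshare(data))
  J <- n_components(data)
  if (length(theta) != J)
    stop(sprintf("'theta' must have length J = %d", J), call. = FALSE)
  check_theta(theta)
  n <- n_systems(data)
  m <- gaps_matrix(data)
  d2 <- vapply(seq_len(J), function(col) {
    j <- col - 1L
    k <- J - j
    y <- m[, col]
    th <- theta[col]
    -2 * n / th^2 - (k - 1) * sum((1 + y)^2 / (th + 1 + th * y)^2) +
      n * k / (th + 1)^2
  }, numeric(1))
  diag(d2, nrow = J)
}

#' Newton-Raphson baseline for the load-sharing likelihood
#'
#' Maximises the observed log-likelihood jointly over all `J` stage
#' parameters by the undamped Newton update
#' `theta <- theta - solve(H, score)`. The default is deliberately
#' unsafeguarded — no line search, no positivity projection — so the
#' iteration's sensitivity to starting values is observable rather than
#' hidden: an iterate that leaves the parameter space or blows up is
#' reported as a status, never raised as an error.
#'
#' With `safeguarded = TRUE` the step is halved until the log-likelihood
#' does not decrease and all parameters stay positive, giving an honest
#' "repaired" Newton for comparison.
#'
#' @param data a [loadshare] object.
#' @param theta0 vector of `J` positive starting values.
#' @param tol convergence threshold on the sup-norm of the score.
#' @param max_iter iteration cap.
#' @param safeguarded logical; use step-halving with a positivity guard.
#' @return an object of class `nr_report`: `status` (one of
#'   `"converged"`, `"nonpositive-parameter"`, `"diverged"`,
#'   `"max-iter"`), `start`, `estimates` (populated for `"converged"`
#'   and `"max-iter"`, otherwise `NA`), `last_valid` (last iterate inside
#'   the parameter space), `loglik` (at `estimates` when populated,
#'   otherwise `NA`), `iterations`.
#' @examples
#' d <- table1_gaps()
#' nr_fit(d, theta0 = c(0.004, 1.25, 2.98, 3.89, 4.24))
#' nr_fit(d, theta0 = rep(0.9, 5))  # typically fails undamped
#' @export
nr_fit <- function(data, theta0, tol = 1e-8, max_iter = 500L,
                   safeguarded = FALSE) {
  stopifnot(is_loadshare(data))
  J <- n_components(data)
  if (length(theta0) != J)
    stop(sprintf("'theta0' must have length J = %d", J), call. = FALSE)
  check_theta(theta0)
  theta <- theta0
  last_valid <- theta0
  status <- "max-iter"
  s <- 0L
  while (s < max_iter) {
    s <- s + 1L
    sc <- loadshare_score(theta, data)
    if (max(abs(sc)) < tol) {
      status <- "converged"
      break
    }
    H <- loadshare_hessian(theta, data)
    step <- tryCatch(solve(H, sc), error = function(e) rep(NaN, J))
    theta_new <- theta - step
    if (safeguarded) {
      ll_old <- loadshare_loglik(theta, data)
      lam <- 1
      repeat {
        cand <- theta - lam * step
        ok <- all(is.finite(cand)) && all(cand > 0) &&
          loadshare_loglik(cand, data) >= ll_old
        if (ok || lam < 1e-12) break
        lam <- lam / 2
      }
      if (lam < 1e-12) {
        status <- "diverged"
        break
      }
      theta_new <- theta - lam * step
    }
    if (any(!is.finite(theta_new))) {
      status <- "diverged"
      break
    }
    if (any(theta_new <= 0)) {
      status <- "nonpositive-parameter"
      break
    }
    theta <- theta_new
    last_valid <- theta
  }
  populated <- status %in% c("converged", "max-iter")
  structure(list(method = "nr",
                 status = status,
                 start = theta0,
                 estimates = if (populated) theta else rep(NA_real_, J),
                 last_valid = last_valid,
                 loglik = if (populated) loadshare_loglik(theta, data)
                          else NA_real_,
                 iterations = s,
                 converged = status == "converged"),
            class = "nr_report")
}

#' @export
print.nr_report <- function(x, digits = 5, ...) {
  cat(sprintf("Newton-Raphson fit: status = %s (%d iterations)\n",
              x$status, x$iterations))
  if (!anyNA(x$estimates)) {
    est <- round(x$estimates, digits)
    names(est) <- paste0("theta_", seq_along(est) - 1L)
    print(est)
    cat(sprintf("log-likelihood: %.4f\n", x$loglik))
  }
  invisible(x)
}
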