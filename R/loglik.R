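#' Stage density of the gap time in a load-sharing system
#'
#' During stage `j` of a `J`-component system, `J - j` surviving
#' components with i.i.d. Lindley(`theta`) residual lifetimes compete for
#' the next failure; the observed gap is their minimum, with density
#' \deqn{f_{Y^{(j)}}(y) = (J - j)\, h(y)\, S(y)^{J - j},}
#' where `h` and `S` are the Lindley hazard and survival functions. For
#' the last stage (`J - j = 1`) this collapses to the plain Lindley
#' density.
#'
#' @param y positive gap time(s).
#' @param j stage index, `0 <= j <= J - 1`.
#' @param J number of components in the system.
#' @param theta positive stage parameter.
#' @param log logical; return the log density?
#' @return the (log) density of the stage-`j` gap time.
#' @examples
#' dstage(2, j = 0, J = 3, theta = 0.5)
#' dstage(2, j = 2, J = 3, theta = 0.5) == dlindley(2, 0.5)
#' @export
dstage <- function(y, j, J, theta, log = FALSE) {
  if (length(j) != 1L || length(J) != 1L || j < 0 || j > J - 1)
    stop("stage index must satisfy 0 <= j <= J - 1", call. = FALSE)
  if (any(y <= 0))
    stop("gap times must be strictly positive", call. = FALSE)
  k <- J - j
  ld <- base::log(k) + hlindley(y, theta, log = TRUE) +
    k * slindley(y, theta, log.p = TRUE)
  if (log) ld else exp(ld)
}

#' Observed-data log-likelihood of the load-sharing model
#'
#' `loadshare_loglik` evaluates the full observed-data log-likelihood
#' \deqn{\ell(\Theta) = \sum_{i=1}^n \sum_{j=0}^{J-1}
#'   \log f_{Y^{(j)}}(y_i^{(j)}),}
#' the sum of log stage densities over systems and stages, *including*
#' the additive constant \eqn{n \sum_j \log(J - j)} that proportional
#' ("up to a constant") likelihood displays drop. All reported
#' log-likelihoods in this package use this full convention; on real
#' data the likelihood itself is astronomically small (e.g. around
#' 1e-148), so all arithmetic stays in log space and the likelihood is
#' only ever materialised as `exp(loglik)` for display.
#'
#' The likelihood factorises over stages — each stage term depends on a
#' single parameter — so `stage_loglik` gives the stage-`j` contribution
#' and `sum over j of stage_loglik` equals `loadshare_loglik`. This
#' factorisation is what lets the EM estimator fit each stage as an
#' independent one-dimensional problem.
#'
#' @param theta numeric vector of `J` positive stage parameters
#'   `(theta_0, ..., theta_{J-1})`.
#' @param data a [loadshare] object.
#' @param theta_j positive scalar parameter of stage `j`.
#' @param j stage index, counted from 0.
#' @return scalar log-likelihood.
#' @examples
#' d <- table1_gaps()
#' loadshare_loglik(c(0.00837, 0.01994, 0.03099, 0.03908, 0.05589), d)
#' @export
loadshare_loglik <- function(theta, data) {
  stopifnot(is_loadshare(data))
  J <- n_components(data)
  if (length(theta) != J)
    stop(sprintf("'theta' must have length J = %d", J), call. = FALSE)
  check_theta(theta)
  sum(vapply(seq_len(J) - 1L, function(j) stage_loglik(theta[j + 1L], j, data),
             numeric(1)))
}

#' @rdname loadshare_loglik
#' @export
stage_loglik <- function(theta_j, j, data) {
  stopifnot(is_loadshare(data))
  J <- n_components(data)
  if (j < 0 || j > J - 1)
    stop("stage index must satisfy 0 <= j <= J - 1", call. = FALSE)
  y <- gaps_matrix(data)[, j + 1L]
  sum(dstage(y, j, J, theta_j, log = TRUE))
}
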