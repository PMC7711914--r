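#' Simulate gap-time data from the load-sharing model
#'
#' For each system `i` and stage `j`, draws `J - j` i.i.d.
#' Lindley(`thetas[j + 1]`) residual lifetimes by inverse-CDF sampling
#' and records their minimum as the stage-`j` gap. Stages are generated
#' independently: after each failure the survivors restart with fresh
#' i.i.d. lifetimes under the new stage parameter (the equal
#' load-sharing assumption — no carried-over work history).
#'
#' Reproducibility discipline: each `(system, stage)` cell gets its own
#' RNG substream seeded deterministically from `seed`, so enlarging `n`
#' or `J` extends a data set without reshuffling the draws already made;
#' the caller's RNG state is saved and restored. The defaults are the
#' reference study condition: ten five-component systems with stage
#' parameters 0.01, 0.02, 0.03, 0.04, 0.05.
#'
#' @param n number of systems (rows).
#' @param thetas vector of `J` positive stage parameters.
#' @param seed integer master seed (mandatory).
#' @return a [loadshare] object with `n` rows and `length(thetas)`
#'   columns.
#' @examples
#' d <- simulate_loadshare(10, c(0.01, 0.02, 0.03, 0.04, 0.05), seed = 42)
#' dim(d)
#' @export
simulate_loadshare <- function(n = 10,
                               thetas = c(0.01, 0.02, 0.03, 0.04, 0.05),
                               seed) {
  if (missing(seed) || length(seed) != 1L || !is.finite(seed))
    stop("an integer 'seed' is required", call. = FALSE)
  if (length(n) != 1L || n < 1)
    stop("'n' must be a positive count", call. = FALSE)
  check_theta(thetas)
  J <- length(thetas)
  if (J > 126L)
    stop("at most 126 components supported by the substream scheme",
         call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  gaps <- matrix(NA_real_, n, J)
  for (i in seq_len(n)) {
    for (col in seq_len(J)) {
      j <- col - 1L
      set.seed(cell_seed(seed, i, j))
      gaps[i, col] <- min(rlindley(J - j, thetas[col]))
    }
  }
  loadshare(gaps)
}

# deterministic per-(system, stage) substream seed; unique for j <= 126
cell_seed <- function(seed, i, j) {
  (abs(as.integer(seed)) + 1000003 * i + 7919 * j) %% 2147483647
}
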