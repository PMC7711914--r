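#' Gap-time data for an equal load-sharing parallel system
#'
#' A `loadshare` object holds the observed gap times of `n` independent
#' `J`-component parallel systems run to total failure. Entry `(i, j)` of
#' the matrix is the time between the j-th and (j+1)-st failure of system
#' i (stage `j`, counted from 0). During stage `j` there are `J - j`
#' surviving components; under the equal load-sharing rule their residual
#' lifetimes are i.i.d. Lindley with stage parameter `theta[j + 1]`, and
#' the observed gap is their minimum.
#'
#' Systems are exchangeable: no component identity is stored, only gap
#' times enter the likelihood. All gaps must be strictly positive and
#' finite — zero gaps are rejected at load time because the log stage
#' density is undefined at the boundary.
#'
#' @param gaps numeric matrix (or data frame) with one row per system and
#'   one column per stage; all entries strictly positive and finite.
#' @param x object to test, print, or convert.
#' @param ... unused.
#' @return `loadshare()` returns a validated object of class `loadshare`:
#'   the gap matrix with attributes `n` (systems) and `J` (components per
#'   system).
#' @examples
#' d <- loadshare(matrix(c(5, 3, 7, 2), nrow = 2))
#' n_systems(d); n_components(d)
#' @export
loadshare <- function(gaps) {
  if (is.data.frame(gaps)) gaps <- as.matrix(gaps)
  if (!is.matrix(gaps) || !is.numeric(gaps))
    stop("'gaps' must be a numeric matrix (systems x stages)", call. = FALSE)
  if (nrow(gaps) < 1L || ncol(gaps) < 1L)
    stop("need at least one system and one stage", call. = FALSE)
  if (any(!is.finite(gaps)))
    stop("all gap times must be finite", call. = FALSE)
  if (any(gaps <= 0))
    stop("all gap times must be strictly positive", call. = FALSE)
  dimnames(gaps) <- list(NULL, paste0("gap_", seq_len(ncol(gaps)) - 1L))
  structure(gaps, class = c("loadshare", "matrix", "array"),
            n = nrow(gaps), J = ncol(gaps))
}

#' @rdname loadshare
#' @export
is_loadshare <- function(x) inherits(x, "loadshare")

#' @rdname loadshare
#' @export
n_systems <- function(x) {
  stopifnot(is_loadshare(x))
  nrow(x)
}

#' @rdname loadshare
#' @export
n_components <- function(x) {
  stopifnot(is_loadshare(x))
  ncol(x)
}

#' @rdname loadshare
#' @export
print.loadshare <- function(x, ...) {
  cat(sprintf("Load-sharing gap times: %d systems, J = %d components\n",
              nrow(x), ncol(x)))
  print(unclass(x)[seq_len(min(6L, nrow(x))), , drop = FALSE], ...)
  if (nrow(x) > 6L) cat(sprintf("... and %d more systems\n", nrow(x) - 6L))
  invisible(x)
}

gaps_matrix <- function(x) {
  m <- unclass(x)
  attr(m, "n") <- NULL
  attr(m, "J") <- NULL
  m
}

#' Read and write gap-time matrices as CSV
#'
#' The canonical layout is systems-as-rows: a header
#' `system,gap_0,...,gap_{J-1}` and one row per system. Tables printed
#' stages-as-rows (one row per stage `Y(0..J-1)`, one column per system,
#' header `stage,system_1,...,system_n`) are read with
#' `transposed = TRUE`. Lines starting with `#` are treated as comments.
#'
#' @param file path to a CSV file.
#' @param transposed logical; set `TRUE` when rows are stages rather than
#'   systems.
#' @param x a [loadshare] object.
#' @return `read_gaps` returns a [loadshare] object; `write_gaps`
#'   invisibly returns `file`.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_gaps(loadshare(matrix(1:6 + 0.5, nrow = 3)), f)
#' read_gaps(f)
#' @export
read_gaps <- function(file, transposed = FALSE) {
  df <- utils::read.csv(file, comment.char = "#", check.names = FALSE)
  if (ncol(df) < 2L)
    stop("gap-time CSV needs an id column plus at least one value column",
         call. = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (transposed) m <- t(m)
  loadshare(m)
}

#' @rdname read_gaps
#' @export
write_gaps <- function(x, file, transposed = FALSE) {
  stopifnot(is_loadshare(x))
  m <- gaps_matrix(x)
  if (transposed) {
    df <- data.frame(stage = paste0("Y", seq_len(ncol(m)) - 1L), t(m),
                     check.names = FALSE)
    names(df)[-1L] <- paste0("system_", seq_len(nrow(m)))
  } else {
    df <- data.frame(system = seq_len(nrow(m)), m, check.names = FALSE)
  }
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Bundled gap-time data sets
#'
#' `table1_gaps()` returns the printed n = 10, J = 5 gap-time data set
#' used throughout the examples: ten five-component systems generated
#' from stage parameters (0.01, 0.02, 0.03, 0.04, 0.05). It is shipped
#' exactly as printed (stages-as-rows) and transposed to the canonical
#' systems-as-rows layout on read.
#'
#' `example_j3_gaps()` returns a SYNTHETIC three-component example data
#' set (n = 25) generated by [simulate_loadshare()] at stage parameters
#' (0.036, 0.041, 0.069), on the scale of published three-component
#' load-sharing analyses. It is a stand-in for demonstration of
#' [real_data_analysis()], not a real measurement.
#'
#' @return a [loadshare] object.
#' @examples
#' table1_gaps()
#' @export
table1_gaps <- function() {
  read_gaps(system.file("extdata", "table1_lifetimes.csv",
                        package = "lindleyLS", mustWork = TRUE),
            transposed = TRUE)
}

#' @rdname table1_gaps
#' @export
example_j3_gaps <- function() {
  read_gaps(system.file("extdata", "loadshare_J3_synthetic.csv",
                        package = "lindleyLS", mustWork = TRUE))
}
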