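#' @useDynLib csmprage, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft mvfft rnorm runif sd var cor kmeans quantile
#' @importFrom utils write.csv read.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_arg <- function(...) stop(sprintf(...), call. = FALSE)

#' Derive a child RNG seed from a base seed and integer tags
#'
#' Deterministic integer mixing so that adding sessions, repeats or protocols
#' to a sweep never perturbs the seeds of existing ones. All arithmetic stays
#' below 2^53 so the result is exact in double precision; the output lies in
#' 1..(2^31 - 2) and is safe for `set.seed()`.
#'
#' @param base integer base seed.
#' @param ... further integer tags (session, repeat, protocol index, role...).
#' @return a single integer seed.
#' @export
derive_seed <- function(base, ...) {
  tags <- c(base, ...)
  m <- 2147483629  # prime below 2^31
  h <- 104729
  mult <- c(40503, 10007, 20011, 30011, 50021, 70001, 90001, 11003)
  for (i in seq_along(tags)) {
    k <- mult[((i - 1L) %% length(mult)) + 1L]
    h <- (h * 31 + (as.numeric(tags[i]) %% m) * k) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

# Root mean square error between two arrays, optionally within a mask.
rmse <- function(a, b, mask = NULL) {
  d <- (a - b)^2
  if (!is.null(mask)) d <- d[mask]
  sqrt(mean(d))
}

# Dice overlap of two logical masks.
dice <- function(a, b) {
  2 * sum(a & b) / (sum(a) + sum(b))
}

# Voxel coordinate grids for a 3D shape (1-based indices).
coord_grids <- function(shape) {
  list(
    x = array(rep(seq_len(shape[1]), times = shape[2] * shape[3]), dim = shape),
    y = array(rep(rep(seq_len(shape[2]), each = shape[1]), times = shape[3]), dim = shape),
    z = array(rep(seq_len(shape[3]), each = shape[1] * shape[2]), dim = shape)
  )
}
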