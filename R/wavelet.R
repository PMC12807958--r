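#' Orthogonal wavelet filter coefficients
#'
#' Analysis low-pass filter taps for the supported orthogonal families. The
#' 8-tap Daubechies-4 filter is the package default for reconstruction.
#'
#' @param family one of "db4" (8 taps), "db2" (4 taps), "haar".
#' @return numeric vector of low-pass taps (sums to sqrt(2), unit 2-norm).
#' @export
wavelet_filter <- function(family = "db4") {
  switch(family,
    db4 = c(0.2303778133088965, 0.7148465705529157, 0.6308807679298589,
            -0.0279837694168599, -0.1870348117190931, 0.0308413818355608,
            0.0328830116668852, -0.0105974017850690),
    db2 = c(0.4829629131445341, 0.8365163037378079,
            0.2241438680420134, -0.1294095225512604),
    haar = c(1, 1) / sqrt(2),
    stop_arg("unknown wavelet family '%s'", family)
  )
}

# Single-level periodic analysis matrix of size n x n (n even): first n/2 rows
# are shifted low-pass filters (stride 2), last n/2 rows the matching
# high-pass (quadrature mirror) filters. Orthogonal by construction.
dwt_level_matrix <- function(n, h) {
  stopifnot(n %% 2 == 0)
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1)   # high-pass via alternating flip
  A <- matrix(0, n, n)
  for (k in seq_len(n / 2)) {
    idx <- ((2 * (k - 1) + seq_len(L) - 1) %% n) + 1
    for (j in seq_len(L)) {
      A[k, idx[j]] <- A[k, idx[j]] + h[j]
      A[n / 2 + k, idx[j]] <- A[n / 2 + k, idx[j]] + g[j]
    }
  }
  A
}

#' Feasible decomposition depth for a periodic DWT
#'
#' Caps the requested depth so every subband length stays an even integer.
#' @param n signal length.
#' @param levels requested depth.
#' @return integer depth actually usable.
#' @export
dwt_max_levels <- function(n, levels = 4) {
  lev <- 0; m <- n
  while (m %% 2 == 0 && lev < levels && m >= 2) { m <- m / 2; lev <- lev + 1 }
  lev
}

#' Multi-level orthogonal DWT matrix
#'
#' Returns the n x n orthogonal matrix of a `levels`-deep periodic discrete
#' wavelet transform: `w = W %*% x` stacks, from top, the level-`levels`
#' approximation followed by detail bands coarse-to-fine. `t(W)` inverts it.
#' Levels are capped so every subband length stays an integer; a warning is
#' issued when the cap bites.
#'
#' @param n signal length.
#' @param family wavelet family, see [wavelet_filter()].
#' @param levels requested decomposition depth (default 4).
#' @return orthogonal n x n matrix with attributes `levels`, `family`,
#'   `coarse_len` (length of the final approximation band).
#' @export
dwt_matrix <- function(n, family = "db4", levels = 4) {
  h <- wavelet_filter(family)
  max_lev <- dwt_max_levels(n, levels)
  if (max_lev < levels)
    warning(sprintf("dwt_matrix: %d levels not divisible for n=%d, using %d",
                    levels, n, max_lev))
  W <- diag(n)
  m <- n
  for (l in seq_len(max_lev)) {
    A <- diag(n)
    A[1:m, 1:m] <- dwt_level_matrix(m, h)
    W <- A %*% W
    m <- m / 2
  }
  attr(W, "levels") <- max_lev
  attr(W, "family") <- family
  attr(W, "coarse_len") <- m
  W
}

#' 2D separable orthogonal DWT (and inverse) via transform matrices
#'
#' `dwt2(x, Wr, Wc)` computes `Wr %*% x %*% t(Wc)`; `idwt2` applies the
#' transposes. Works for real or complex matrices.
#'
#' @param x matrix (nrow(Wr) columns must match, etc.).
#' @param Wr,Wc DWT matrices for rows and columns from [dwt_matrix()].
#' @return transformed matrix of the same shape.
#' @export
dwt2 <- function(x, Wr, Wc = Wr) Wr %*% x %*% t(Wc)

#' @rdname dwt2
#' @export
idwt2 <- function(x, Wr, Wc = Wr) t(Wr) %*% x %*% Wc

#' Complex-aware soft thresholding
#'
#' The proximal operator of `tau * ||.||_1`: shrinks magnitudes by `tau`
#' towards zero and preserves phase for complex input.
#'
#' @param w numeric or complex array.
#' @param tau threshold (>= 0).
#' @return array of the same shape.
#' @export
soft_threshold <- function(w, tau) {
  if (tau < 0) stop_arg("threshold tau must be >= 0")
  if (is.complex(w)) {
    m <- Mod(w)
    sc <- ifelse(m > tau, (m - tau) / pmax(m, .Machine$double.eps), 0)
    w * sc
  } else {
    sign(w) * pmax(abs(w) - tau, 0)
  }
}

# Logical mask (as matrix) of the coarse approximation block of a 2D DWT with
# the given transform matrices.
coarse_band_mask <- function(Wr, Wc = Wr) {
  cr <- attr(Wr, "coarse_len"); cc <- attr(Wc, "coarse_len")
  m <- matrix(FALSE, nrow(Wr), nrow(Wc))
  m[seq_len(cr), seq_len(cc)] <- TRUE
  m
}
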