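test_that("DWT matrices are orthogonal and invert exactly", {
  for (n in c(16, 48, 64)) {
    W <- dwt_matrix(n)
    expect_lt(max(abs(t(W) %*% W - diag(n))), 1e-10)
    x <- rnorm(n)
    expect_lt(max(abs(t(W) %*% (W %*% x) - x)), 1e-10)
  }
  # complex round-trip through the 2D wrappers
  set.seed(4)
  x <- matrix(complex(real = rnorm(48^2), imaginary = rnorm(48^2)), 48)
  W <- dwt_matrix(48)
  expect_lt(max(Mod(idwt2(dwt2(x, W), W) - x)), 1e-10)
})

test_that("level-1 transform agrees with a direct periodic convolution oracle", {
  n <- 32
  h <- wavelet_filter("db4")
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1)
  set.seed(11)
  x <- rnorm(n)
  # oracle: a_k = sum_j h_j x_{(2k-2+j-1) mod n + 1}
  a <- vapply(seq_len(n / 2), function(k)
    sum(h * x[((2 * (k - 1) + seq_len(L) - 1) %% n) + 1]), 0)
  d <- vapply(seq_len(n / 2), function(k)
    sum(g * x[((2 * (k - 1) + seq_len(L) - 1) %% n) + 1]), 0)
  W1 <- dwt_matrix(n, levels = 1)
  expect_equal(as.numeric(W1 %*% x), c(a, d), tolerance = 1e-12)
})

test_that("the compiled filter-bank transform matches the matrix transform", {
  set.seed(2)
  for (n in c(16, 48)) {
    W <- dwt_matrix(n)
    lev <- attr(W, "levels")
    x <- matrix(complex(real = rnorm(n^2), imaginary = rnorm(n^2)), n)
    fb <- csmprage:::dwt2_fb_cpp(x, wavelet_filter("db4"), lev, lev, FALSE)
    expect_lt(max(Mod(fb - W %*% x %*% t(W))), 1e-12)
    back <- csmprage:::dwt2_fb_cpp(fb, wavelet_filter("db4"), lev, lev, TRUE)
    expect_lt(max(Mod(back - x)), 1e-12)
  }
})

test_that("soft thresholding shrinks magnitudes and preserves phase", {
  expect_equal(soft_threshold(3, 1), 2)
  expect_equal(soft_threshold(-0.5, 1), 0)
  z <- 4 * exp(1i * pi / 3)
  expect_equal(soft_threshold(z, 1), 3 * exp(1i * pi / 3), tolerance = 1e-12)
  expect_error(soft_threshold(1, -0.1), "tau")
  # vector case, real
  expect_equal(soft_threshold(c(-2, 0.2, 2), 0.5), c(-1.5, 0, 1.5))
})

test_that("the compiled mixed-radix FFT matches R's fft", {
  set.seed(3)
  for (n in c(16, 48, 96)) {
    x <- matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n)
    expect_lt(max(Mod(csmprage:::fft2_mr_cpp(x, FALSE) - fft(x))), 1e-9)
    expect_lt(max(Mod(csmprage:::fft2_mr_cpp(x, TRUE) -
                        fft(x, inverse = TRUE) / length(x))), 1e-9)
  }
})
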