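test_that("GL weight recursion reproduces known coefficient sequences", {
  expect_equal(gl_weights(0, 5), c(1, 0, 0, 0, 0))
  expect_equal(gl_weights(1, 5), c(1, -1, 0, 0, 0))
  expect_equal(gl_weights(2, 6), c(1, -2, 1, 0, 0, 0))
  expect_equal(gl_weights(0.5, 4), c(1, -0.5, -0.125, -0.0625))
  # half-order weights against binomial coefficients via the gamma function
  k <- 0:9
  binom <- (-1)^k * gamma(0.5 + 1) / (gamma(k + 1) * gamma(0.5 - k + 1))
  expect_equal(gl_weights(0.5, 10), binom, tolerance = 1e-12)
})

test_that("first-difference weights telescope to zero partial sums", {
  w <- gl_weights(1, 30)
  sums <- cumsum(w)
  expect_true(all(abs(sums[-1]) < 1e-15))
})

test_that("integer-order derivatives reduce to identity and first difference", {
  ss <- toy_spectra(3, 40, seed = 11)
  d0 <- fractional_derivative(ss, 0)
  expect_identical(d0$values, ss$reflectance)

  x <- c(0.2, 0.5, 0.4)
  s3 <- spectra_set(matrix(x, 1), 350:352)
  d1 <- fractional_derivative(s3, 1)
  expect_equal(d1$values[1, 2:3], c(0.3, -0.1), tolerance = 1e-14)

  dfull <- fractional_derivative(ss, 1)
  expect_equal(dfull$values[, -1],
               t(apply(ss$reflectance, 1, diff)), tolerance = 1e-12)
})

test_that("fractional orders match a naive double-loop summation", {
  set.seed(42)
  for (alpha in c(0.3, 0.5, 1.5, 2)) {
    x <- runif(20)
    ss <- spectra_set(matrix(x, 1), seq(350, length.out = 20))
    d <- fractional_derivative(ss, alpha)
    expect_equal(d$values[1, ], naive_gl(x, alpha), tolerance = 1e-12)
  }
})

test_that("grid step enters as h^(-alpha)", {
  x <- runif(15, 0.1, 0.5)
  s1 <- spectra_set(matrix(x, 1), seq(350, length.out = 15, by = 1))
  s2 <- spectra_set(matrix(x, 1), seq(350, length.out = 15, by = 2))
  a <- 0.7
  expect_equal(fractional_derivative(s2, a)$values,
               fractional_derivative(s1, a)$values * 2^(-a),
               tolerance = 1e-12)
})

test_that("GL differentiation is linear in the spectra", {
  sx <- toy_spectra(2, 30, seed = 5)
  sy <- toy_spectra(2, 30, seed = 6)
  for (alpha in c(0.5, 1.2)) {
    lhs <- fractional_derivative(
      spectra_set(3 * sx$reflectance - 2 * sy$reflectance, sx$wavelengths),
      alpha)$values
    rhs <- 3 * fractional_derivative(sx, alpha)$values -
      2 * fractional_derivative(sy, alpha)$values
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("applying order 1 twice agrees with order 2", {
  ss <- toy_spectra(4, 50, seed = 9)
  d1 <- fractional_derivative(ss, 1)
  d11 <- fractional_derivative(
    spectra_set(d1$values, ss$wavelengths, ss$sample_ids), 1)
  d2 <- fractional_derivative(ss, 2)
  expect_equal(d11$values[, 3:50], d2$values[, 3:50], tolerance = 1e-10)
})

test_that("order bounds and truncation behave", {
  ss <- toy_spectra(1, 20)
  expect_error(fractional_derivative(ss, -0.1), "alpha")
  expect_error(fractional_derivative(ss, 2.5), "alpha")
  # truncation caps the history: keeping all terms changes nothing
  expect_equal(fractional_derivative(ss, 0.5, truncation = 20)$values,
               fractional_derivative(ss, 0.5)$values)
  # a 1-term window at alpha = 0.5 is just the scaled signal
  expect_equal(fractional_derivative(ss, 0.5, truncation = 1)$values,
               ss$reflectance)
})

test_that("SG smoothing reproduces polynomials up to the fit order", {
  wl <- seq(350, length.out = 41)
  quad <- 0.3 + 0.001 * (wl - 370) + 2e-5 * (wl - 370)^2
  ss <- spectra_set(rbind(quad, rep(0.25, 41)), wl)
  sm <- sg_smooth(ss, window_length = 9, polyorder = 2)
  expect_equal(sm$reflectance[1, ], quad, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(sm$reflectance[2, ], rep(0.25, 41), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("SG smoothing equals explicit per-window least squares", {
  set.seed(13)
  y <- sin(seq(0, 4, length.out = 41)) / 3 + 0.4 + rnorm(41, 0, 0.03)
  ss <- spectra_set(matrix(y, 1), seq(350, length.out = 41))
  sm <- sg_smooth(ss, 9, 2)$reflectance[1, ]
  # interior: fit a quadratic to each 9-point window, evaluate at the centre
  oracle <- vapply(5:37, function(c) {
    idx <- (c - 4):(c + 4)
    unname(stats::predict(stats::lm(y[idx] ~ stats::poly(idx, 2, raw = TRUE)),
                          data.frame(idx = c)))
  }, numeric(1))
  expect_equal(sm[5:37], oracle, tolerance = 1e-10)
  # edges: polynomial fit of the terminal window evaluated at edge positions
  dfl <- data.frame(i = 1:9, y = y[1:9])
  left <- stats::lm(y ~ i + I(i^2), dfl)
  expect_equal(sm[1:4],
               unname(stats::predict(left, data.frame(i = 1:4))),
               tolerance = 1e-10)
  dfr <- data.frame(i = 33:41, y = y[33:41])
  right <- stats::lm(y ~ i + I(i^2), dfr)
  expect_equal(sm[38:41],
               unname(stats::predict(right, data.frame(i = 38:41))),
               tolerance = 1e-10)
})

test_that("SG rejects bad window parameters", {
  ss <- toy_spectra(1, 20)
  expect_error(sg_smooth(ss, window_length = 8), "odd")
  expect_error(sg_smooth(ss, window_length = 9, polyorder = 9), "polyorder")
  expect_error(sg_smooth(toy_spectra(1, 5), window_length = 9), "shorter")
})

test_that("preprocess_spectra returns smoothed plus one set per order", {
  ss <- toy_spectra(3, 60, seed = 2)
  prep <- preprocess_spectra(ss)
  expect_named(prep$derivatives,
               c("order_0", "order_0.5", "order_1", "order_1.5", "order_2"))
  expect_identical(prep$derivatives$order_0$values, prep$smoothed$reflectance)
  expect_equal(dim(prep$derivatives$order_2$values), dim(ss$reflectance))
})
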