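# constant-reflectance spectra_set covering all index bands
flat_spectra <- function(level, n = 2) {
  spectra_set(matrix(level, n, length(350:900)), 350:900)
}

test_that("empirical indices evaluate their printed formulas", {
  # piecewise-constant spectrum with distinct levels at the named bands
  wl <- 350:900
  r <- rep(0.2, length(wl))
  lev <- c(`445` = 0.05, `530` = 0.11, `531` = 0.12, `550` = 0.15,
           `570` = 0.13, `670` = 0.08, `680` = 0.09, `700` = 0.18,
           `705` = 0.20, `750` = 0.42, `800` = 0.45)
  for (nm in names(lev)) r[wl == as.numeric(nm)] <- lev[[nm]]
  ss <- spectra_set(rbind(r, r), wl)
  idx <- compute_empirical_indices(ss)
  expect_equal(idx$CARI[1], (0.18 - 0.08) - 0.2 * (0.18 + 0.08))
  expect_equal(idx$GRVI[1], 0.45 / 0.15)
  expect_equal(idx$PRI[1], (0.13 - 0.11) / (0.13 + 0.11))
  expect_equal(idx$IPVI[1], 0.45 / (0.45 + 0.08))
  expect_equal(idx$PRI1[1], (0.12 - 0.13) / (0.12 + 0.13))
  expect_equal(idx$SR1[1], 0.42 / 0.18)
  expect_equal(idx$SR3[1], 0.42 / 0.15)
  expect_equal(idx$SR705[1], 0.42 / 0.20)
  expect_equal(idx$SR680[1], 0.45 / 0.09)
  expect_equal(idx$SIPI[1], (0.45 - 0.05) / (0.45 - 0.09))
  # the as-printed IPVI product form stays available behind the flag
  idxp <- compute_empirical_indices(ss, ipvi_form = "product")
  expect_equal(idxp$IPVI[1], 0.45 * (0.45 + 0.08))
})

test_that("ratio identities and degenerate spectra behave", {
  # equal numerator/denominator bands give unit ratios
  flat <- compute_empirical_indices(flat_spectra(0.3))
  expect_equal(flat$GRVI, c(1, 1))
  expect_equal(flat$SR1, c(1, 1))
  expect_equal(flat$PRI, c(0, 0))
  expect_equal(flat$PRI1, c(0, 0))
  expect_equal(flat$CARI, -0.2 * 0.6 * c(1, 1))
  # SIPI is 0/0 on a constant spectrum: flagged non-finite, not an error
  expect_false(any(is.finite(flat$SIPI)))
})

test_that("indices error when the grid lacks a required band", {
  narrow <- spectra_set(matrix(0.3, 1, length(500:900)), 500:900)
  expect_error(compute_empirical_indices(narrow), "not on grid")
})

test_that("trilateral parameters collapse correctly on simple spectra", {
  wl <- 350:800
  # strictly linear spectrum: first derivative is constant
  slope <- 5e-4
  lin <- 0.05 + slope * (wl - 350)
  ss <- spectra_set(rbind(lin, lin), wl)
  d1 <- fractional_derivative(ss, 1)
  tri <- compute_trilateral(ss, d1)
  expect_equal(tri$Db[1], slope, tolerance = 1e-12)
  expect_equal(tri$Dy[1], slope, tolerance = 1e-12)
  expect_equal(tri$Dr[1], slope, tolerance = 1e-12)
  expect_equal(tri$SDr[1], slope * 91, tolerance = 1e-10)  # 670..760 inclusive
  expect_equal(tri$SDb[1], slope * 41, tolerance = 1e-10)  # 490..530
  expect_equal(tri$Rg[1], lin[wl == 560])
  expect_equal(tri$Rr[1], lin[wl == 650])

  # constant spectrum: all derivative features vanish, ratio is flagged
  cs <- spectra_set(matrix(0.3, 1, length(wl)), wl)
  trif <- compute_trilateral(cs, fractional_derivative(cs, 1))
  expect_equal(trif$Db, 0)
  expect_equal(trif$SDr, 0)
  expect_equal(trif$SDr_minus_SDb, 0)
  expect_true(is.na(trif$SDr_over_SDy))
})

test_that("Dr equals a brute-force scan on a vegetation-like spectrum", {
  d <- generate_dataset(small_config(seed = 6, n_samples = 5))
  prep <- preprocess_spectra(d$spectra, orders = c(0, 1))
  tri <- compute_trilateral(prep$smoothed, prep$derivatives$order_1)
  wl <- prep$smoothed$wavelengths
  red <- which(wl >= 670 & wl <= 760)
  for (s in 1:5) {
    dv <- prep$derivatives$order_1$values[s, ]
    best <- -Inf
    for (k in red) if (dv[k] > best) best <- dv[k]
    expect_equal(tri$Dr[s], best)
    expect_true(wl[red[which.max(dv[red])]] >= 670 &&
                wl[red[which.max(dv[red])]] <= 760)
  }
})

test_that("trilateral preconditions are enforced", {
  ss <- toy_spectra(1, 100)  # 350-449 nm only
  d1 <- fractional_derivative(ss, 1)
  expect_error(compute_trilateral(ss, d1), "outside grid")
  full <- spectra_set(matrix(0.3, 1, length(350:800)), 350:800)
  expect_error(
    compute_trilateral(full, fractional_derivative(full, 0.5)), "order 1")
})

test_that("two-band DI and SAVI evaluate and antisymmetrise", {
  X <- rbind(c(0.5, 0.3, 0.1), c(0.2, 0.2, 0.4))
  dv <- as_deriv(X, order = 0.5, wl_start = 700)
  expect_equal(two_band_values(dv, "DI", 700, 701), c(0.2, 0))
  expect_equal(two_band_values(dv, "SAVI", 700, 701),
               c(1.16 * 0.2 / 0.96, 0))
  # antisymmetry over random pairs
  set.seed(21)
  Xr <- matrix(runif(40), 8, 5)
  dvr <- as_deriv(Xr)
  for (kind in c("DI", "SAVI")) {
    for (p in list(c(350, 353), c(351, 352))) {
      expect_equal(two_band_values(dvr, kind, p[1], p[2]),
                   -two_band_values(dvr, kind, p[2], p[1]),
                   tolerance = 1e-14)
    }
  }
  # SAVI flags an exactly-zero denominator
  Xz <- rbind(c(-0.08, -0.08), c(0.1, 0.2))
  dvz <- as_deriv(Xz)
  v <- two_band_values(dvz, "SAVI", 350, 351)
  expect_false(is.finite(v[1]))
  expect_true(is.finite(v[2]))
})
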