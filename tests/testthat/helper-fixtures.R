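# shared fixtures: everything is generated in code, no stored data

# random spectra_set on an integer-nm grid starting at 350
toy_spectra <- function(n_samples, n_bands, seed = 1, lo = 0.05, hi = 0.6) {
  set.seed(seed)
  spectra_set(matrix(runif(n_samples * n_bands, lo, hi), n_samples),
              wavelengths = seq(350, by = 1, length.out = n_bands))
}

# wrap a plain matrix as a derivative_set (for screening tests)
as_deriv <- function(values, order = 1, wl_start = 350) {
  structure(
    list(order = order,
         wavelengths = seq(wl_start, by = 1, length.out = ncol(values)),
         sample_ids = paste0("S", seq_len(nrow(values))),
         values = values),
    class = "derivative_set")
}

# independent O(n^2) Grunwald-Letnikov oracle: direct double-loop summation
naive_gl <- function(x, alpha, h = 1) {
  n <- length(x)
  w <- gl_weights(alpha, n)
  out <- numeric(n)
  for (t in seq_len(n)) {
    s <- 0
    for (k in 0:(t - 1)) s <- s + w[k + 1] * x[t - k]
    out[t] <- s / h^alpha
  }
  out
}

# brute-force band-pair correlation matrix via pearson_r on each pair
brute_pair_r <- function(X, y, kind) {
  B <- ncol(X)
  out <- matrix(NA_real_, B, B)
  for (i in seq_len(B)) {
    for (j in seq_len(B)) {
      v <- if (kind == "DI") X[, i] - X[, j]
           else 1.16 * (X[, i] - X[, j]) / (X[, i] + X[, j] + 0.16)
      if (all(is.finite(v)) && stats::sd(v) > 0) out[i, j] <- stats::cor(v, y)
    }
  }
  out
}

# small-grid synthetic config for fast model-stage tests
small_config <- function(seed = 1, n_samples = 24) {
  synthetic_config(n_samples = n_samples, seed = seed,
                   wl_start = 350, wl_end = 900, wl_step = 1)
}
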