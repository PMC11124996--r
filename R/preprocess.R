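#' Savitzky-Golay smoothing of a spectra set
#'
#' Replaces each spectrum by its local least-squares polynomial fit
#' (Savitzky-Golay filter). Terminal windows are handled by evaluating the
#' window polynomial at the edge positions, so the output grid is unchanged.
#'
#' @param spectra a [spectra_set()].
#' @param window_length odd window width in bands (default 9).
#' @param polyorder polynomial degree, must be smaller than `window_length`
#'   (default 2).
#' @return a smoothed [spectra_set()] on the same grid.
#' @export
sg_smooth <- function(spectra, window_length = 9, polyorder = 2) {
  stopifnot(inherits(spectra, "spectra_set"))
  if (window_length %% 2 != 1) stop("window_length must be odd")
  if (polyorder >= window_length) stop("polyorder must be < window_length")
  if (ncol(spectra$reflectance) < window_length) {
    stop("spectrum shorter than the smoothing window")
  }
  sm <- t(apply(spectra$reflectance, 1, signal::sgolayfilt,
                p = polyorder, n = window_length))
  spectra_set(sm, spectra$wavelengths, spectra$sample_ids)
}

#' Grunwald-Letnikov fractional-difference weights
#'
#' The GL fractional derivative of order `alpha` is a weighted sum over the
#' signal's history; the weights are signed generalized binomial
#' coefficients, generated by the recursion `w_0 = 1`,
#' `w_k = w_{k-1} * (k - 1 - alpha) / k`.
#'
#' At integer orders the weights terminate: `alpha = 0` gives the identity
#' `(1, 0, 0, ...)` and `alpha = 1` the backward first difference
#' `(1, -1, 0, ...)`.
#'
#' @param alpha differentiation order.
#' @param n_terms number of weights to return (>= 1).
#' @return numeric vector of the first `n_terms` GL weights.
#' @export
gl_weights <- function(alpha, n_terms) {
  stopifnot(n_terms >= 1)
  w <- numeric(n_terms)
  w[1] <- 1
  if (n_terms > 1) {
    k <- seq_len(n_terms - 1)
    w <- cumprod(c(1, (k - 1 - alpha) / k))
  }
  w
}

#' Grunwald-Letnikov fractional-order derivative of spectra
#'
#' Applies the GL construction band-wise along wavelength: for band index
#' `t` (1-based) the derivative is
#' `h^(-alpha) * sum_{k=0}^{t-1} w_k * R(t - k)`,
#' using the full available history back to the series start (expanding
#' window at the left boundary). `alpha = 0` returns the input unchanged;
#' `alpha = 1` reproduces the backward first difference divided by `h` at
#' every band after the first.
#'
#' Left-boundary values (bands with short history) are retained rather than
#' masked so band indices are stable across orders.
#'
#' @param spectra a [spectra_set()] (typically already SG-smoothed).
#' @param alpha differentiation order in `[0, 2]`.
#' @param truncation optional history length cap (number of GL terms kept);
#'   `Inf` (default) keeps the full history.
#' @return a `derivative_set`: list with `order`, `wavelengths`,
#'   `sample_ids`, and `values` (`n_samples x n_bands`, units
#'   reflectance / nm^alpha).
#' @export
fractional_derivative <- function(spectra, alpha, truncation = Inf) {
  stopifnot(inherits(spectra, "spectra_set"))
  if (!is.finite(alpha) || alpha < 0 || alpha > 2) {
    stop("alpha must lie in [0, 2]")
  }
  h <- grid_step(spectra)
  R <- spectra$reflectance
  B <- ncol(R)
  w <- gl_weights(alpha, B)
  if (is.finite(truncation) && truncation < B) {
    w[(truncation + 1):B] <- 0
  }
  # out[, t] = sum_k w_k R[, t - k]  ==  R %*% T with T upper-triangular
  # Toeplitz, T[r, c] = w[c - r + 1] for c >= r
  Tm <- matrix(0, B, B)
  shift <- col(Tm) - row(Tm)
  keep <- shift >= 0
  Tm[keep] <- w[shift[keep] + 1]
  vals <- (R %*% Tm) * h^(-alpha)
  structure(
    list(order = alpha, wavelengths = spectra$wavelengths,
         sample_ids = spectra$sample_ids, values = vals),
    class = "derivative_set"
  )
}

#' @export
print.derivative_set <- function(x, ...) {
  cat(sprintf("derivative_set (alpha = %g): %d samples x %d bands\n",
              x$order, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Smooth and differentiate at a set of fractional orders
#'
#' Convenience wrapper for the standard preprocessing sequence: SG smoothing
#' first, then GL differentiation at each requested order (order 0 is the
#' smoothed spectrum itself).
#'
#' @param spectra a [spectra_set()].
#' @param orders numeric vector of GL orders (default `seq(0, 2, by = 0.5)`).
#' @param window_length,polyorder SG parameters, see [sg_smooth()].
#' @param truncation GL history cap, see [fractional_derivative()].
#' @return list with `smoothed` (a [spectra_set()]) and `derivatives`
#'   (named list of `derivative_set`, names like `"order_0.5"`).
#' @export
preprocess_spectra <- function(spectra, orders = seq(0, 2, by = 0.5),
                               window_length = 9, polyorder = 2,
                               truncation = Inf) {
  sm <- sg_smooth(spectra, window_length, polyorder)
  derivs <- lapply(orders, function(a) {
    fractional_derivative(sm, a, truncation = truncation)
  })
  names(derivs) <- paste0("order_", orders)
  list(smoothed = sm, derivatives = derivs)
}
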