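#' Construct a spectra set
#'
#' A `spectra_set` holds reflectance spectra for a batch of samples on a
#' shared, uniform, strictly ascending wavelength grid. It is the common
#' currency of the whole pipeline: the synthetic generator emits one, the
#' preprocessing stage smooths and differentiates one, and the index and
#' band-screening stages consume one (or its derivative counterpart).
#'
#' @param reflectance numeric matrix, `n_samples x n_bands`, dimensionless
#'   reflectance. All values must be finite.
#' @param wavelengths numeric vector of band centres in nm; strictly
#'   increasing with a constant step.
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to `S1, S2, ...`.
#'
#' @return An object of class `spectra_set`: a list with elements
#'   `sample_ids`, `wavelengths`, `reflectance`.
#' @export
spectra_set <- function(reflectance, wavelengths, sample_ids = NULL) {
  reflectance <- as.matrix(reflectance)
  storage.mode(reflectance) <- "double"
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != ncol(reflectance)) {
    stop("length(wavelengths) must equal ncol(reflectance)")
  }
  check_uniform_grid(wavelengths)
  if (!all(is.finite(reflectance))) {
    stop("reflectance contains non-finite values")
  }
  if (is.null(sample_ids)) {
    sample_ids <- paste0("S", seq_len(nrow(reflectance)))
  }
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(reflectance)) {
    stop("length(sample_ids) must equal nrow(reflectance)")
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicated sample_id: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  dimnames(reflectance) <- NULL
  structure(
    list(sample_ids = sample_ids, wavelengths = wavelengths,
         reflectance = reflectance),
    class = "spectra_set"
  )
}

# wavelength grid must be strictly increasing with constant step
check_uniform_grid <- function(wavelengths, tol = 1e-8) {
  if (length(wavelengths) == 0) stop("empty wavelength grid")
  if (anyNA(wavelengths)) stop("wavelength grid contains NA")
  if (length(wavelengths) == 1) return(invisible(wavelengths))
  d <- diff(wavelengths)
  if (any(d <= 0)) {
    bad <- which(d <= 0)[1]
    stop(sprintf("wavelength grid not strictly increasing at %g -> %g",
                 wavelengths[bad], wavelengths[bad + 1]))
  }
  if (max(d) - min(d) > tol * max(abs(wavelengths))) {
    bad <- which.max(abs(d - d[1]))
    stop(sprintf(
      "non-uniform wavelength grid: step changes near columns %g, %g, %g nm",
      wavelengths[bad], wavelengths[bad + 1],
      wavelengths[min(bad + 2, length(wavelengths))]))
  }
  invisible(wavelengths)
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("spectra_set: %d samples x %d bands (%g-%g nm, step %g nm)\n",
              nrow(x$reflectance), ncol(x$reflectance),
              min(x$wavelengths), max(x$wavelengths), grid_step(x)))
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$reflectance)

grid_step <- function(x) {
  wl <- if (inherits(x, "spectra_set") || inherits(x, "derivative_set")) {
    x$wavelengths
  } else {
    as.numeric(x)
  }
  if (length(wl) < 2) return(1)
  wl[2] - wl[1]
}

#' Look up band column indices for exact wavelengths
#'
#' Band access is exact integer-nm matching on the grid; no interpolation is
#' performed (the canonical grid is already at 1 nm resolution).
#'
#' @param x a `spectra_set` or `derivative_set`.
#' @param wavelengths wavelengths (nm) to locate.
#' @return integer column indices.
#' @keywords internal
band_index <- function(x, wavelengths) {
  idx <- match(wavelengths, x$wavelengths)
  if (anyNA(idx)) {
    stop("wavelength(s) not on grid: ",
         paste(wavelengths[is.na(idx)], collapse = ", "),
         " (grid covers ", min(x$wavelengths), "-", max(x$wavelengths), " nm)")
  }
  idx
}

#' Extract reflectance at one wavelength across samples
#' @param x a `spectra_set` or `derivative_set`.
#' @param wavelength single wavelength in nm (must be on the grid).
#' @return numeric vector, one value per sample.
#' @export
band <- function(x, wavelength) {
  values_matrix(x)[, band_index(x, wavelength)]
}

values_matrix <- function(x) {
  if (inherits(x, "spectra_set")) x$reflectance else x$values
}
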