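#' Pearson correlation with zero-variance flagging
#'
#' Standard product-moment correlation; returns `NA` (flagged undefined)
#' instead of erroring when either vector has zero variance, which the
#' screening stages treat as an excluded cell.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation in `[-1, 1]`, or `NA` if undefined.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3) stop("need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) return(NA_real_)
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Exhaustive two-band index correlation screening
#'
#' For every ordered band pair `(i, j)` of a derivative-transformed spectra
#' set, computes the Pearson correlation between the two-band index
#' (DI or SAVI, see [two_band_values()]) and a trait vector, and locates the
#' pair maximising `|r|`. Ties are broken deterministically by smallest `i`,
#' then smallest `j`. Undefined cells (zero index variance, zero SAVI
#' denominator) are excluded from the argmax.
#'
#' The full grid is computed band-by-band in compiled code, so peak working
#' memory is one `n_samples x n_bands` block plus the output matrix.
#'
#' @param deriv a `derivative_set`.
#' @param kind `"DI"` or `"SAVI"`.
#' @param target numeric trait vector, one value per sample.
#' @param keep_matrix keep the full `n_bands x n_bands` r matrix in the
#'   result (default TRUE; turn off in long multi-seed loops to save
#'   memory).
#' @return object of class `two_band_correlation`: list with `kind`,
#'   `order`, `r_max`, `i_max`, `j_max` (nm), and `r_matrix` (or NULL).
#' @export
two_band_correlation <- function(deriv, kind = c("DI", "SAVI"), target,
                                 keep_matrix = TRUE) {
  stopifnot(inherits(deriv, "derivative_set"))
  kind <- match.arg(kind)
  if (length(target) != nrow(deriv$values)) {
    stop("target length must equal the number of samples")
  }
  if (any(!is.finite(target))) stop("target contains non-finite values")
  rmat <- pair_correlation_cpp(deriv$values, cbind(as.numeric(target)),
                               kind)[[1]]
  best <- argmax_abs(rmat, deriv$wavelengths)
  structure(
    list(kind = kind, order = deriv$order,
         r_max = best$r, i_max = best$i, j_max = best$j,
         r_matrix = if (keep_matrix) rmat else NULL),
    class = "two_band_correlation"
  )
}

#' @export
print.two_band_correlation <- function(x, ...) {
  cat(sprintf("%s, order %g: r_max = %.3f at (%g, %g) nm\n",
              x$kind, x$order, x$r_max, x$i_max, x$j_max))
  invisible(x)
}

# |r| argmax with smallest-i-then-smallest-j tie breaking; NaN excluded
argmax_abs <- function(rmat, wavelengths) {
  m <- abs(rmat)
  m[!is.finite(m)] <- -Inf
  best <- max(m)
  if (!is.finite(best)) {
    stop("selection error: every band-pair correlation is undefined")
  }
  hits <- which(m == best, arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  ri <- hits[1, 1]; rj <- hits[1, 2]
  list(r = rmat[ri, rj], i = wavelengths[ri], j = wavelengths[rj])
}

# screen one derivative set against several traits in a single compiled pass
two_band_screen <- function(deriv, kind, targets) {
  targets <- as.matrix(targets)
  mats <- pair_correlation_cpp(deriv$values, targets, kind)
  lapply(seq_len(ncol(targets)), function(t) {
    best <- argmax_abs(mats[[t]], deriv$wavelengths)
    list(kind = kind, order = deriv$order,
         r_max = best$r, i_max = best$i, j_max = best$j)
  })
}

#' Rank features by correlation magnitude with a trait
#'
#' Computes [pearson_r()] between each feature column and the target and
#' sorts by `|r|` descending (signed r is reported). Features with an
#' undefined correlation sort last. `|r|` rather than signed r is the
#' criterion because strongly negative features are as informative to the
#' downstream regressions as positive ones.
#'
#' @param features data.frame or matrix of feature columns (named).
#' @param target numeric trait vector.
#' @param k number of top features to return (default all).
#' @return data.frame with `feature`, `r`, `abs_r`, sorted by `abs_r`
#'   descending; top `k` rows.
#' @export
rank_features <- function(features, target, k = ncol(as.data.frame(features))) {
  features <- as.data.frame(features)
  features <- features[, setdiff(names(features), "sample_id"), drop = FALSE]
  if (ncol(features) == 0) stop("empty feature table")
  if (k > ncol(features)) stop("k exceeds the number of features")
  r <- vapply(features, function(col) {
    v <- suppressWarnings(as.numeric(col))
    if (any(!is.finite(v))) NA_real_ else pearson_r(v, target)
  }, numeric(1))
  out <- data.frame(feature = names(features), r = unname(r),
                    abs_r = abs(unname(r)), stringsAsFactors = FALSE)
  out <- out[order(-ifelse(is.na(out$abs_r), -Inf, out$abs_r), out$feature), ]
  rownames(out) <- NULL
  out[seq_len(k), , drop = FALSE]
}

#' Assemble the four model-input feature combinations
#'
#' Combination 1: top-k empirical vegetation indices; combination 2: top-k
#' trilateral parameters; combination 3: top-k two-band
#' fractional-derivative indices (pooled across DI/SAVI and orders);
#' combination 4: top-k of the pooled union of all three families. Each
#' family's candidates must already be ranked (see [rank_features()]).
#'
#' @param empirical,trilateral,twoband ranked data.frames (`feature`, `r`,
#'   `abs_r`).
#' @param k members per combination (default 7).
#' @return named list of four data.frames (`combination_1` ..
#'   `combination_4`), each with exactly `k` rows sorted by `abs_r`
#'   descending.
#' @export
build_combinations <- function(empirical, trilateral, twoband, k = 7) {
  fam <- list(empirical = empirical, trilateral = trilateral,
              twoband = twoband)
  for (nm in names(fam)) {
    if (nrow(fam[[nm]]) < k) {
      stop(sprintf("family '%s' has only %d features, need %d",
                   nm, nrow(fam[[nm]]), k))
    }
  }
  top <- function(df) {
    df <- df[order(-ifelse(is.na(df$abs_r), -Inf, df$abs_r), df$feature), ]
    rownames(df) <- NULL
    df[seq_len(k), , drop = FALSE]
  }
  pooled <- rbind(empirical, trilateral, twoband)
  list(
    combination_1 = top(empirical),
    combination_2 = top(trilateral),
    combination_3 = top(twoband),
    combination_4 = top(pooled)
  )
}
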