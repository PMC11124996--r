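#' Empirical vegetation indices
#'
#' Computes the ten fixed-band vegetation indices used for chlorophyll
#' screening, from (smoothed) reflectance:
#' \tabular{ll}{
#'   CARI  \tab (R700 - R670) - 0.2 (R700 + R670) \cr
#'   GRVI  \tab R800 / R550 \cr
#'   PRI   \tab (R570 - R530) / (R570 + R530) \cr
#'   IPVI  \tab R800 / (R800 + R670)  (ratio form, default) \cr
#'   PRI1  \tab (R531 - R570) / (R531 + R570) \cr
#'   SR1   \tab R750 / R700 \cr
#'   SR3   \tab R750 / R550 \cr
#'   SR705 \tab R750 / R705 \cr
#'   SR680 \tab R800 / R680 \cr
#'   SIPI  \tab (R800 - R445) / (R800 - R680)
#' }
#' `ipvi_form = "product"` switches IPVI to `R800 * (R800 + R670)`, a form
#' seen in print where the division bar was lost in typesetting; the ratio
#' form is the one defined in the index's source literature. Division by
#' zero yields a non-finite value which is propagated as missing rather
#' than erroring.
#'
#' @param smoothed a [spectra_set()] whose grid covers 445-800 nm.
#' @param ipvi_form `"ratio"` (default) or `"product"`.
#' @return data.frame, one row per sample, columns `sample_id` plus the ten
#'   indices.
#' @export
compute_empirical_indices <- function(smoothed, ipvi_form = c("ratio", "product")) {
  stopifnot(inherits(smoothed, "spectra_set"))
  ipvi_form <- match.arg(ipvi_form)
  R <- function(nm) band(smoothed, nm)  # band_index() errors on bad coverage
  r445 <- R(445); r530 <- R(530); r531 <- R(531); r550 <- R(550)
  r570 <- R(570); r670 <- R(670); r680 <- R(680); r700 <- R(700)
  r705 <- R(705); r750 <- R(750); r800 <- R(800)
  ipvi <- if (ipvi_form == "ratio") r800 / (r800 + r670) else r800 * (r800 + r670)
  data.frame(
    sample_id = smoothed$sample_ids,
    CARI = (r700 - r670) - 0.2 * (r700 + r670),
    GRVI = r800 / r550,
    PRI = (r570 - r530) / (r570 + r530),
    IPVI = ipvi,
    PRI1 = (r531 - r570) / (r531 + r570),
    SR1 = r750 / r700,
    SR3 = r750 / r550,
    SR705 = r750 / r705,
    SR680 = r800 / r680,
    SIPI = (r800 - r445) / (r800 - r680),
    stringsAsFactors = FALSE
  )
}

#' Red-edge "trilateral" spectral parameters
#'
#' Scalar features of the blue-edge, yellow-edge and red-edge regions,
#' computed from smoothed reflectance and its first derivative:
#' \itemize{
#'   \item `Db`: max first derivative on 490-530 nm (blue edge);
#'   \item `Dy`: max first derivative on the yellow-edge window (default
#'     462-642 nm as tabulated in the source literature; the conventional
#'     560-640 nm window is available via `dy_range`);
#'   \item `Dr`: max first derivative on 670-760 nm (red edge);
#'   \item `Rg`: max reflectance on 510-560 nm (green peak);
#'   \item `Rr`: min reflectance on 650-690 nm (red well);
#'   \item `SDb`, `SDy`, `SDr`: sums of first-derivative values over the
#'     same windows (endpoints inclusive);
#'   \item `SDr_minus_SDb` and `SDr_over_SDy` (the ratio is NA-flagged when
#'     `SDy` is 0).
#' }
#'
#' @param smoothed a [spectra_set()].
#' @param first_deriv the matching order-1 `derivative_set`.
#' @param dy_range yellow-edge window in nm, default `c(462, 642)`.
#' @return data.frame, one row per sample.
#' @export
compute_trilateral <- function(smoothed, first_deriv, dy_range = c(462, 642)) {
  stopifnot(inherits(smoothed, "spectra_set"),
            inherits(first_deriv, "derivative_set"))
  if (abs(first_deriv$order - 1) > 1e-12) {
    stop("first_deriv must have order 1")
  }
  wl <- smoothed$wavelengths
  in_range <- function(lo, hi) which(wl >= lo & wl <= hi)
  rng_check <- function(lo, hi) {
    if (lo < min(wl) || hi > max(wl)) {
      stop(sprintf("range %g-%g nm outside grid", lo, hi))
    }
  }
  rng_check(490, 530); rng_check(dy_range[1], dy_range[2])
  rng_check(670, 760); rng_check(510, 560); rng_check(650, 690)

  D <- first_deriv$values
  Rm <- smoothed$reflectance
  blue <- in_range(490, 530)
  yellow <- in_range(dy_range[1], dy_range[2])
  red <- in_range(670, 760)

  sdy <- rowSums(D[, yellow, drop = FALSE])
  sdb <- rowSums(D[, blue, drop = FALSE])
  sdr <- rowSums(D[, red, drop = FALSE])
  ratio <- ifelse(sdy == 0, NA_real_, sdr / sdy)
  data.frame(
    sample_id = smoothed$sample_ids,
    Db = apply(D[, blue, drop = FALSE], 1, max),
    Dy = apply(D[, yellow, drop = FALSE], 1, max),
    Dr = apply(D[, red, drop = FALSE], 1, max),
    Rg = apply(Rm[, in_range(510, 560), drop = FALSE], 1, max),
    Rr = apply(Rm[, in_range(650, 690), drop = FALSE], 1, min),
    SDb = sdb, SDy = sdy, SDr = sdr,
    SDr_minus_SDb = sdr - sdb,
    SDr_over_SDy = ratio,
    stringsAsFactors = FALSE
  )
}

#' Two-band spectral index values
#'
#' Evaluates an arbitrary two-band index on an order-alpha transformed
#' spectrum: the difference index `DI(i, j) = R_i - R_j`, or the
#' soil-adjusted index `SAVI(i, j) = (1 + L)(R_i - R_j)/(R_i + R_j + L)`
#' with `L = 0.16`. `R` here is the fractional-derivative-transformed
#' reflectance, so DI/SAVI at order 0 reduce to the plain smoothed-band
#' forms. A SAVI denominator of exactly zero yields a non-finite value for
#' that sample.
#'
#' @param deriv a `derivative_set` (any order, including 0).
#' @param kind `"DI"` or `"SAVI"`.
#' @param i,j band wavelengths in nm (must be on the grid).
#' @return numeric vector, one value per sample.
#' @export
two_band_values <- function(deriv, kind = c("DI", "SAVI"), i, j) {
  stopifnot(inherits(deriv, "derivative_set"))
  kind <- match.arg(kind)
  ri <- band(deriv, i)
  rj <- band(deriv, j)
  if (kind == "DI") ri - rj else 1.16 * (ri - rj) / (ri + rj + 0.16)
}
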