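#' Chlorophyll content from ethanol-extract absorbances
#'
#' Converts spectrophotometric absorbances at 663 and 645 nm of a 100%
#' ethanol extract into chlorophyll a, b and total content, expressed per
#' unit of `m` (fresh weight in g, or leaf area in dm^2). Extract
#' concentrations (mg/L) follow the Arnon-style coefficients
#' \deqn{C_a = 12.7 D_{663} - 2.69 D_{645}}
#' \deqn{C_b = 22.9 D_{645} - 4.68 D_{663}}
#' \deqn{C_t = 20.21 D_{645} + 8.02 D_{663}}
#' and content is `C * (volume_mL / 1000) / m`; with the standard 25 mL
#' extract this is `C / (40 m)`.
#'
#' The coefficient sets satisfy `chl_a + chl_b = chl_total` exactly
#' (12.7 - 4.68 = 8.02 and 22.9 - 2.69 = 20.21). A transposed variant of the
#' C_b equation that circulates in some method sections (`22.9 D663 -
#' 4.68 D645`) breaks that identity; it is available via
#' `as_printed = TRUE` for fidelity checks only.
#'
#' @param d663,d645 absorbances (>= 0).
#' @param m normalising quantity: fresh weight (g) for LCC_W, leaf area
#'   (dm^2) for LCC_A. Must be > 0.
#' @param volume_mL final extract volume (default 25).
#' @param as_printed use the transposed C_b coefficient ordering.
#' @return list with `chl_a`, `chl_b`, `chl_total` (mg per unit of `m`) and
#'   logical `flagged` marking physically impossible (negative) contents.
#' @export
chlorophyll_content <- function(d663, d645, m, volume_mL = 25,
                                as_printed = FALSE) {
  if (any(!is.finite(m)) || any(m <= 0)) stop("m must be > 0")
  if (any(d663 < 0) || any(d645 < 0)) stop("absorbances must be >= 0")
  ca <- 12.7 * d663 - 2.69 * d645
  cb <- if (as_printed) 22.9 * d663 - 4.68 * d645 else 22.9 * d645 - 4.68 * d663
  ct <- 20.21 * d645 + 8.02 * d663
  scale <- (volume_mL / 1000) / m
  out <- list(chl_a = ca * scale, chl_b = cb * scale, chl_total = ct * scale)
  out$flagged <- out$chl_a < 0 | out$chl_b < 0
  out
}

#' Area- and weight-based chlorophyll expressions for one record
#'
#' Computes LCC_A (m = leaf area, dm^2), LCC_W (m = fresh weight, g) and
#' their ratio SLW = LCC_A / LCC_W (specific leaf weight, g/dm^2) from one
#' absorbance pair. When `leaf_area` is missing, the default area of nine
#' 1-cm-diameter leaf disks (0.070686 dm^2) is used.
#'
#' @param d663,d645 absorbances.
#' @param fresh_weight fresh weight in g (> 0).
#' @param leaf_area leaf area in dm^2 (> 0); default nine 1-cm disks.
#' @param volume_mL extract volume (default 25).
#' @return list with `lcc_area` (mg/dm^2), `lcc_weight` (mg/g), `slw`
#'   (g/dm^2).
#' @export
lcc_pair <- function(d663, d645, fresh_weight, leaf_area = default_leaf_area(),
                     volume_mL = 25) {
  if (any(!is.finite(fresh_weight)) || any(fresh_weight <= 0)) {
    stop("fresh_weight must be > 0")
  }
  if (any(!is.finite(leaf_area)) || any(leaf_area <= 0)) {
    stop("leaf_area must be > 0")
  }
  lcc_area <- chlorophyll_content(d663, d645, m = leaf_area,
                                  volume_mL = volume_mL)$chl_total
  lcc_weight <- chlorophyll_content(d663, d645, m = fresh_weight,
                                    volume_mL = volume_mL)$chl_total
  list(lcc_area = lcc_area, lcc_weight = lcc_weight,
       slw = lcc_area / lcc_weight)
}

#' Default leaf-disk area
#'
#' Nine 1-cm-diameter disks: `9 * pi * 0.25` cm^2 = 0.070686 dm^2.
#' @return area in dm^2.
#' @export
default_leaf_area <- function() 9 * pi * 0.25 / 100
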