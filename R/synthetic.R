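#' Configuration for the synthetic canopy-spectra generator
#'
#' The generator emulates the statistical structure the pipeline assumes of
#' field canopy spectra at the potato tuber-formation stage: chlorophyll-
#' driven absorption wells in the visible, a red edge whose inflection
#' wavelength shifts with chlorophyll, a leaf-water absorption dip near
#' 1450 nm, and a fresh-weight chlorophyll expression (LCC_W) that inherits
#' water-driven variability absent from the area-based expression (LCC_A).
#'
#' @param n_samples number of samples (default 60).
#' @param seed integer RNG seed.
#' @param wl_start,wl_end,wl_step wavelength grid in nm (default 350-1830,
#'   step 1).
#' @param lcca_range chlorophyll per unit leaf area, mg/dm^2 (default
#'   `c(32, 55)`).
#' @param slw_range specific leaf weight, g/dm^2 (default `c(13, 27)`).
#' @param water_sd relative sd of the leaf-water latent (default 0.10).
#' @param noise_sd_additive additive reflectance noise sd (default 0.004).
#' @param noise_sd_multiplicative relative multiplicative noise sd
#'   (default 0.01).
#' @param red_edge_shift_per_chl red-edge inflection shift, nm per mg/dm^2
#'   of chlorophyll (default 0.4).
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_samples = 60, seed = 1,
                             wl_start = 350, wl_end = 1830, wl_step = 1,
                             lcca_range = c(32, 55),
                             slw_range = c(13, 27),
                             water_sd = 0.10,
                             noise_sd_additive = 0.004,
                             noise_sd_multiplicative = 0.01,
                             red_edge_shift_per_chl = 0.4) {
  stopifnot(wl_step > 0, n_samples >= 4,
            lcca_range[1] < lcca_range[2], slw_range[1] < slw_range[2],
            water_sd >= 0, noise_sd_additive >= 0,
            noise_sd_multiplicative >= 0)
  structure(
    list(n_samples = as.integer(n_samples), seed = as.integer(seed),
         wl_start = wl_start, wl_end = wl_end, wl_step = wl_step,
         lcca_range = lcca_range, slw_range = slw_range,
         water_sd = water_sd,
         noise_sd_additive = noise_sd_additive,
         noise_sd_multiplicative = noise_sd_multiplicative,
         red_edge_shift_per_chl = red_edge_shift_per_chl),
    class = "synthetic_config"
  )
}

#' Closed-form pseudo-vegetation reflectance model
#'
#' Deterministic, noise-free canopy reflectance on a wavelength grid, built
#' from documented components:
#' \itemize{
#'   \item a NIR plateau whose level scales with the `structure` latent;
#'   \item Gaussian chlorophyll absorption wells centred near 450 nm and
#'     670 nm with saturating (Beer-Lambert-style) depth in `chl_area`,
#'     leaving a green relative maximum near 550 nm;
#'   \item a logistic red-edge ramp between the visible level and the NIR
#'     plateau whose inflection wavelength increases linearly with
#'     `chl_area` at `red_edge_shift_per_chl` nm per mg/dm^2;
#'   \item water-scaled Gaussian absorption dips near 1200 and 1450 nm.
#' }
#' By construction, reflectance at 670 nm is strictly decreasing in
#' `chl_area` with all other inputs fixed, and all values lie in `[0, 1]`.
#'
#' This is a mechanistic stand-in with realistic chlorophyll-correlated
#' features, not a radiative-transfer code.
#'
#' @param chl_area chlorophyll per unit leaf area, mg/dm^2 (> 0).
#' @param water leaf-water latent, relative (around 1; 0 disables the water
#'   dips).
#' @param structure canopy-structure latent, dimensionless (around 1).
#' @param wavelengths uniform ascending grid in nm.
#' @param red_edge_shift_per_chl nm of inflection shift per mg/dm^2.
#' @return numeric reflectance vector on `wavelengths`, in `[0, 1]`.
#' @export
reflectance_model <- function(chl_area, water, structure, wavelengths,
                              red_edge_shift_per_chl = 0.4) {
  if (!is.finite(chl_area) || chl_area <= 0) stop("chl_area must be > 0")
  if (length(wavelengths) == 0) stop("empty wavelength grid")
  check_uniform_grid(wavelengths)
  wl <- wavelengths

  # visible: base level minus saturating chlorophyll wells, plus green bump
  depth_red <- 0.20 * (1 - exp(-chl_area / 25))
  depth_blue <- 0.18 * (1 - exp(-chl_area / 20))
  vis <- 0.24 -
    depth_red * exp(-((wl - 670)^2) / (2 * 30^2)) -
    depth_blue * exp(-((wl - 450)^2) / (2 * 40^2)) +
    0.06 * exp(-((wl - 550)^2) / (2 * 25^2))

  # NIR plateau scaled by structure, attenuated by water absorption
  water_abs <- water * (0.30 * exp(-((wl - 1450)^2) / (2 * 40^2)) +
                        0.12 * exp(-((wl - 1200)^2) / (2 * 50^2)))
  nir <- 0.45 * structure * (1 - pmin(water_abs, 0.95))

  # logistic red-edge ramp; inflection tracks chlorophyll
  lambda_re <- 690 + red_edge_shift_per_chl * chl_area
  s <- 1 / (1 + exp(-(wl - lambda_re) / 12))
  refl <- vis * (1 - s) + nir * s
  pmin(pmax(refl, 0), 1)
}

#' Locate the red-edge inflection of a spectrum
#'
#' Finds the first-derivative maximum in the 680-780 nm window and refines
#' it by three-point parabolic interpolation, giving a continuous position
#' estimate on the 1 nm grid.
#'
#' @param reflectance numeric reflectance vector.
#' @param wavelengths matching wavelength grid in nm.
#' @return inflection wavelength in nm.
#' @export
red_edge_position <- function(reflectance, wavelengths) {
  h <- wavelengths[2] - wavelengths[1]
  d <- diff(reflectance) / h
  mid <- wavelengths[-1] - h / 2
  win <- which(mid >= 680 & mid <= 780)
  k <- win[which.max(d[win])]
  if (k <= 1 || k >= length(d)) return(mid[k])
  y1 <- d[k - 1]; y2 <- d[k]; y3 <- d[k + 1]
  denom <- y1 - 2 * y2 + y3
  if (denom == 0) return(mid[k])
  mid[k] + h * 0.5 * (y1 - y3) / denom
}

#' Generate a labeled synthetic spectra dataset
#'
#' Draws per-sample latents, renders noise-free spectra with
#' [reflectance_model()], then applies multiplicative and additive Gaussian
#' noise. Latents:
#' \itemize{
#'   \item `chl_area` uniform on `lcca_range` (this is LCC_A exactly);
#'   \item `water` ~ Normal(1, `water_sd`), truncated to be positive;
#'   \item specific leaf weight `slw = slw_base / water` with `slw_base`
#'     uniform on `slw_range` scaled so that higher leaf water lowers SLW;
#'   \item `structure` ~ Normal(1, 0.05).
#' }
#' `LCC_W = chl_area / slw`, so the fresh-weight expression inherits the
#' water-driven variability while the area-based expression does not.
#' Absorbances at 663/645 nm are back-computed from the ethanol-extraction
#' equations assuming a chlorophyll a:b ratio of 3:1, together with
#' consistent `fresh_weight` and `leaf_area` columns, so the chlorophyll
#' module recovers LCC_A and LCC_W exactly from the label table.
#'
#' Identical config (including seed) gives bit-identical output.
#'
#' @param config a [synthetic_config()].
#' @return list of class `labeled_spectra` with `spectra` (a
#'   [spectra_set()]), `labels` (data.frame: sample_id, lcc_area,
#'   lcc_weight, d663, d645, fresh_weight, leaf_area, slw), and `truth`
#'   (data.frame of latent chl_area, water, structure, red_edge_nm).
#' @export
generate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_samples
  wl <- seq(config$wl_start, config$wl_end, by = config$wl_step)

  rng <- local({
    set.seed(config$seed)
    list(
      chl = stats::runif(n, config$lcca_range[1], config$lcca_range[2]),
      water = pmax(stats::rnorm(n, 1, config$water_sd), 0.05),
      slw_base = stats::runif(n, config$slw_range[1], config$slw_range[2]),
      structure = stats::rnorm(n, 1, 0.05),
      eps_mult = matrix(stats::rnorm(n * length(wl), 0,
                                     config$noise_sd_multiplicative),
                        n, length(wl)),
      eps_add = matrix(stats::rnorm(n * length(wl), 0,
                                    config$noise_sd_additive),
                       n, length(wl))
    )
  })
  slw <- rng$slw_base / rng$water
  lcc_weight <- rng$chl / slw

  clean <- t(vapply(seq_len(n), function(i) {
    reflectance_model(rng$chl[i], rng$water[i], rng$structure[i], wl,
                      config$red_edge_shift_per_chl)
  }, numeric(length(wl))))
  noisy <- clean * (1 + rng$eps_mult) + rng$eps_add
  noisy <- pmin(pmax(noisy, 0), 1)

  ids <- sprintf("S%02d", seq_len(n))
  leaf_area <- default_leaf_area()
  fresh_weight <- slw * leaf_area
  abso <- absorbance_from_lcc(rng$chl, leaf_area)

  labels <- data.frame(
    sample_id = ids,
    lcc_area = rng$chl,
    lcc_weight = lcc_weight,
    d663 = abso$d663,
    d645 = abso$d645,
    fresh_weight = fresh_weight,
    leaf_area = leaf_area,
    slw = slw,
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    sample_id = ids,
    chl_area = rng$chl,
    water = rng$water,
    structure = rng$structure,
    red_edge_nm = 690 + config$red_edge_shift_per_chl * rng$chl,
    stringsAsFactors = FALSE
  )
  structure(
    list(spectra = spectra_set(noisy, wl, ids),
         clean = spectra_set(pmin(pmax(clean, 0), 1), wl, ids),
         labels = labels, truth = truth, config = config),
    class = "labeled_spectra"
  )
}

#' @export
print.labeled_spectra <- function(x, ...) {
  cat(sprintf(
    "labeled_spectra: %d samples, %d bands; LCC_A %.1f-%.1f mg/dm^2\n",
    nrow(x$labels), length(x$spectra$wavelengths),
    min(x$labels$lcc_area), max(x$labels$lcc_area)))
  invisible(x)
}

# back-compute D663/D645 from a target total chlorophyll content per area,
# assuming chl a : chl b = 3 : 1 and the 25 mL extract volume
absorbance_from_lcc <- function(lcc_area, leaf_area, volume_mL = 25) {
  mass_mg <- lcc_area * leaf_area            # total chlorophyll, mg
  ct <- mass_mg / (volume_mL / 1000)         # extract concentration, mg/L
  ca <- 0.75 * ct
  cb <- 0.25 * ct
  # invert Ca = 12.7 D663 - 2.69 D645 ; Cb = 22.9 D645 - 4.68 D663
  det <- 12.7 * 22.9 - (-2.69) * (-4.68)
  d663 <- (ca * 22.9 + 2.69 * cb) / det
  d645 <- (12.7 * cb + 4.68 * ca) / det
  list(d663 = d663, d645 = d645)
}
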