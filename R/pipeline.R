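#' Correlation screening and feature assembly for each trait
#'
#' Runs the full screening stage on preprocessed spectra: empirical
#' vegetation indices and trilateral parameters from the smoothed spectrum
#' and its first derivative, exhaustive two-band DI/SAVI correlation
#' screening on every derivative order, per-family `|r|` ranking against
#' each trait, and assembly of the four model-input combinations.
#'
#' The two-band candidate pool for a trait consists of the `|r|`-argmax
#' band pair of every (kind, order) grid — one candidate per correlation
#' matrix — mirroring how per-order optimal wavelength combinations are
#' tabulated in this literature.
#'
#' @param prep output of [preprocess_spectra()] (must include an order-1
#'   derivative for the trilateral parameters).
#' @param labels data.frame with `lcc_area` and `lcc_weight` columns (and
#'   any other traits named in `traits`), rows aligned with the spectra.
#' @param traits trait column names to screen (default LCC_A and LCC_W).
#' @param kinds two-band index kinds to screen (default DI and SAVI).
#' @param k combination size (default 7).
#' @return object of class `feature_selection`: list with
#'   \itemize{
#'     \item `twoband_summary`: data.frame (trait, kind, order, r_max,
#'       i_nm, j_nm) — one row per trait and correlation grid;
#'     \item `traits`: per-trait list with `target`, ranked family tables,
#'       `combinations` (four data.frames) and `feature_matrix` (samples x
#'       all candidate features).
#'   }
#' @export
select_features <- function(prep, labels,
                            traits = c("lcc_area", "lcc_weight"),
                            kinds = c("DI", "SAVI"), k = 7) {
  stopifnot(all(traits %in% names(labels)))
  targets <- as.matrix(labels[, traits, drop = FALSE])
  smoothed <- prep$smoothed
  d1 <- Find(function(d) abs(d$order - 1) < 1e-12, prep$derivatives)
  if (is.null(d1)) stop("preprocessing must include an order-1 derivative")

  empirical <- compute_empirical_indices(smoothed)
  trilateral <- compute_trilateral(smoothed, d1)

  # one compiled pass per (kind, order) screens all traits at once
  screen <- list()
  for (kind in kinds) {
    for (dv in prep$derivatives) {
      hits <- two_band_screen(dv, kind, targets)
      for (t in seq_along(traits)) {
        screen[[length(screen) + 1L]] <- data.frame(
          trait = traits[t], kind = kind, order = dv$order,
          r_max = hits[[t]]$r_max, i_nm = hits[[t]]$i_max,
          j_nm = hits[[t]]$j_max, stringsAsFactors = FALSE)
      }
    }
  }
  twoband_summary <- do.call(rbind, screen)

  per_trait <- lapply(traits, function(trait) {
    y <- labels[[trait]]
    tb <- twoband_summary[twoband_summary$trait == trait, , drop = FALSE]
    tb_name <- sprintf("%s_a%g_%g_%g", tb$kind, tb$order, tb$i_nm, tb$j_nm)
    tb_values <- vapply(seq_len(nrow(tb)), function(r) {
      dv <- prep$derivatives[[paste0("order_", tb$order[r])]]
      two_band_values(dv, tb$kind[r], tb$i_nm[r], tb$j_nm[r])
    }, numeric(length(y)))
    colnames(tb_values) <- tb_name
    tb_values <- as.data.frame(tb_values)

    emp_ranked <- rank_features(empirical, y)
    tri_ranked <- rank_features(trilateral, y)
    twb_ranked <- data.frame(feature = tb_name, r = tb$r_max,
                             abs_r = abs(tb$r_max), stringsAsFactors = FALSE)
    twb_ranked <- twb_ranked[order(-twb_ranked$abs_r, twb_ranked$feature), ]
    rownames(twb_ranked) <- NULL

    feature_matrix <- cbind(
      empirical[, setdiff(names(empirical), "sample_id"), drop = FALSE],
      trilateral[, setdiff(names(trilateral), "sample_id"), drop = FALSE],
      tb_values)

    list(target = y,
         ranked = list(empirical = emp_ranked, trilateral = tri_ranked,
                       twoband = twb_ranked),
         combinations = build_combinations(emp_ranked, tri_ranked,
                                           twb_ranked, k = k),
         feature_matrix = feature_matrix)
  })
  names(per_trait) <- traits
  structure(list(twoband_summary = twoband_summary, traits = per_trait),
            class = "feature_selection")
}

#' @export
print.feature_selection <- function(x, ...) {
  cat("feature_selection for traits:",
      paste(names(x$traits), collapse = ", "), "\n")
  best <- x$twoband_summary[order(-abs(x$twoband_summary$r_max)), ]
  cat(sprintf("best two-band feature: %s order %g, r = %.3f at (%g, %g) nm [%s]\n",
              best$kind[1], best$order[1], best$r_max[1],
              best$i_nm[1], best$j_nm[1], best$trait[1]))
  invisible(x)
}

#' Run the whole analysis pipeline on one synthetic dataset
#'
#' Generate -> smooth + differentiate -> screen indices and band pairs ->
#' fit and evaluate the model grid. This is the end-to-end driver used by
#' the analysis scripts and the acceptance checks.
#'
#' @param synth a [synthetic_config()].
#' @param config a [model_config()].
#' @param orders fractional-differentiation orders (default
#'   `seq(0, 2, by = 0.5)`).
#' @param models models to run (default all three).
#' @param combinations combinations to run (default all four).
#' @param k combination size (default 7).
#' @return list with `dataset`, `prep`, `selection`, `metrics`.
#' @export
run_pipeline <- function(synth = synthetic_config(), config = model_config(),
                         orders = seq(0, 2, by = 0.5),
                         models = c("svm", "rf", "bpnn"),
                         combinations = paste0("combination_", 1:4),
                         k = 7) {
  dataset <- generate_dataset(synth)
  prep <- preprocess_spectra(dataset$spectra, orders = orders)
  selection <- select_features(prep, dataset$labels, k = k)
  metrics <- run_experiment(selection, config, models = models,
                            combinations = combinations)
  list(dataset = dataset, prep = prep, selection = selection,
       metrics = metrics)
}
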