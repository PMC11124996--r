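#!/usr/bin/env Rscript
# Stage 3: index computation and correlation screening.
#
# Computes the three spectral feature families (empirical vegetation
# indices, trilateral red-edge parameters, exhaustive two-band DI/SAVI
# indices on every derivative order), correlates each with LCC_A and LCC_W,
# and assembles the four model-input combinations. Writes:
#   results/twoband_optima.csv   - per (trait, kind, order) best band pair
#   results/feature_ranking_<trait>.csv - all candidates ranked by |r|
#   results/combinations_<trait>.csv    - the four 7-member combinations

library(specfrac)

spectra <- read_spectra("results/spectra.csv")
labels <- read_labels("results/labels.csv")
aligned <- align_spectra_labels(spectra, labels)

prep <- preprocess_spectra(aligned$spectra, orders = seq(0, 2, by = 0.5))
sel <- select_features(prep, aligned$labels)

write_labels(sel$twoband_summary, "results/twoband_optima.csv")

for (trait in names(sel$traits)) {
  tr <- sel$traits[[trait]]
  ranking <- rbind(
    cbind(family = "empirical", tr$ranked$empirical),
    cbind(family = "trilateral", tr$ranked$trilateral),
    cbind(family = "twoband", tr$ranked$twoband))
  write_labels(ranking, sprintf("results/feature_ranking_%s.csv", trait))
  combos <- do.call(rbind, Map(cbind, combination = names(tr$combinations),
                               tr$combinations))
  write_labels(combos, sprintf("results/combinations_%s.csv", trait))
}

best <- sel$twoband_summary[order(-abs(sel$twoband_summary$r_max)), ]
cat("Best two-band features per trait:\n")
for (trait in unique(best$trait)) {
  b <- best[best$trait == trait, ][1, ]
  cat(sprintf("  %-10s %s order %.1f: |r| = %.3f at (%g, %g) nm\n",
              trait, b$kind, b$order, abs(b$r_max), b$i_nm, b$j_nm))
}
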