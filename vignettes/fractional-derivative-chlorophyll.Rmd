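---
title: "Estimating canopy chlorophyll from fractional-order derivative spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating canopy chlorophyll from fractional-order derivative spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specfrac)
```

## The problem

Leaf chlorophyll content (LCC) is the standard physiological proxy for crop
photosynthetic capacity and nitrogen status. It is conventionally measured
destructively by ethanol extraction and spectrophotometry, and expressed in
two units: per unit leaf area (LCC\_A, mg·dm⁻²) or per unit fresh weight
(LCC\_W, mg·g⁻¹). The two are linked by the specific leaf weight
SLW = LCC\_A / LCC\_W (g·dm⁻²). Because fresh weight moves with leaf water
status while leaf area does not, LCC\_W confounds chlorophyll with
hydration; one practical question this package addresses is how much more
estimable LCC\_A is than LCC\_W from canopy reflectance.

The estimation route is: smooth each canopy reflectance spectrum
(350–1830 nm at 1 nm), differentiate it at fractional orders 0–2 in steps
of 0.5, build three families of spectral features, screen every feature
against the trait by Pearson correlation, and regress the trait on the
top-ranked features with SVM, random-forest and neural-network models.

## Fractional-order differentiation

Integer-order derivatives of reflectance suppress baseline and amplify
band-edge features, but they skip the continuum of intermediate behaviours.
The Grünwald–Letnikov (GL) construction defines a derivative of arbitrary
order α as a weighted sum over the signal's history:

$$D^\alpha R(t) \;=\; h^{-\alpha} \sum_{k=0}^{t-1} w_k\, R(t-k),
\qquad w_0 = 1,\quad w_k = w_{k-1}\,\frac{k-1-\alpha}{k},$$

with h the grid step (1 nm here). The weights are signed generalized
binomial coefficients; at α = 0 the operator is the identity and at α = 1
it is the backward first difference, so the fractional family interpolates
smoothly between "no transform" and classical derivatives.

Implementation choices that matter:

* **Full-history expanding window.** Each band uses all bands to its left.
  Left-boundary values (few history terms) are retained rather than masked,
  so band indices are stable across orders; the bands the results rely on
  (red edge, NIR) are far from the 350 nm boundary. A `truncation`
  parameter caps the history length for speed if wanted; the default is
  the full series.
* **Smoothing first.** Differentiation amplifies noise, so a
  Savitzky–Golay filter (window 9, polynomial order 2 — mid-range defaults,
  both exposed) is applied before any differentiation, and "order 0" means
  the smoothed spectrum. SG edge handling evaluates the terminal-window
  polynomial at the edge positions, leaving the grid unchanged.
* α is restricted to [0, 2], the range the screening stage uses.

The test suite pins the operator to three independent oracles: the closed
form of the weights, a naive O(n²) double-loop summation, and the exact
composition/telescoping identities at integer orders.

## Spectral feature families

1. **Empirical vegetation indices** (CARI, GRVI, PRI, PRI1, IPVI, SR1,
   SR3, SR705, SR680, SIPI) computed from named bands of the smoothed
   spectrum. IPVI is computed as R800/(R800+R670); a printed product form
   without the division bar circulates and is available behind
   `ipvi_form = "product"` for comparison.
2. **Trilateral parameters**: extrema and areas of the first-derivative
   spectrum over the blue edge (490–530 nm), yellow edge and red edge
   (670–760 nm), plus the green reflectance peak (510–560 nm) and red well
   (650–690 nm). The yellow-edge window defaults to the tabulated
   462–642 nm; the conventional narrower window can be supplied via
   `dy_range` — the package does not silently second-guess the wider
   range. `SDr/SDy` is NA-flagged when `SDy = 0`.
3. **Arbitrary two-band indices** on each derivative order α: the
   difference index DI(i,j) = Rᵢ − Rⱼ and the soil-adjusted index
   SAVI(i,j) = 1.16 (Rᵢ − Rⱼ)/(Rᵢ + Rⱼ + 0.16) (L = 0.16), where R is the
   α-order transformed reflectance. All 1481² ordered band pairs are
   screened; the full matrix (rather than a triangle) is computed so the
   result mirrors the square correlation heatmaps this literature reports,
   and the compiled kernel makes the 2× cost immaterial.

Band lookup is exact integer-nm matching — the canonical grid is already
at 1 nm, so interpolation would only blur provenance.

## Screening and combination assembly

Every feature is scored by Pearson r against the trait; ranking uses |r|,
since a strongly negative feature is as useful to a nonlinear regressor as
a positive one. For the two-band family the |r|-argmax band pair of each
(kind, order) grid is the candidate — one per correlation matrix, ten per
trait — matching how per-order optimal wavelength pairs are tabulated in
this field. Argmax ties break deterministically to the smallest i, then
smallest j; undefined cells (zero variance, zero SAVI denominator) are
excluded, and an all-undefined grid is an error rather than a silent pick.

Four model-input combinations of seven features each are assembled:
top-7 empirical (1), top-7 trilateral (2), top-7 two-band (3), and top-7 of
the pooled union (4). The literature this follows names the four
combinations without enumerating them; this mapping reproduces the
reported orderings (two-band features dominating, pooled close behind) and
is the package's fixed convention.

## Models and evaluation

* **Split**: deterministic target-stratified 2:1 — samples are sorted by
  the trait and the middle member of each consecutive triple goes to
  validation (n = 60 → 40/20). This keeps both splits spanning the trait
  range and the global extremes in the modelling set, and makes every run
  reproducible without a stored split file. `split_seed` selects which
  block member is held out.
* **SVM**: eps-regression, Gaussian kernel, C = 20, γ = 0.02 (polynomial
  kernel selectable). Features are z-scored with modelling-set statistics
  only — validation data never leak into the scaler.
* **RF**: 100 CART trees on raw features.
* **BPNN**: one hidden layer of 10 sigmoid units, linear output, weight
  decay 1e-4, target standardised and back-transformed.
* **Repeated-run averaging**: stochastic learners are refit 10 times under
  distinct seeds and predictions averaged; the split is fixed across
  repeats (only initialisation re-randomises). The SVM is deterministic,
  so one fit suffices.
* **Metrics**: R² = 1 − SS_res/SS_tot, RMSE in trait units, and
  MRE = (100/n) Σ|y−ŷ|/y in percent, on both splits.

## What the synthetic generator emulates — and what it does not

No field spectra are distributed with this package, so the generator
provides datasets with the statistical structure the method assumes:

* n = 60 samples, 350–1830 nm at 1 nm (1481 bands);
* LCC\_A uniform on 32–55 mg·dm⁻², SLW on 13–27 g·dm⁻² — the ranges a
  potato canopy at tuber formation plausibly spans;
* chlorophyll-driven Gaussian absorption wells near 450 and 670 nm with
  saturating Beer–Lambert-style depth, a green maximum near 550 nm;
* a logistic red-edge ramp whose inflection shifts +0.4 nm per mg·dm⁻² of
  chlorophyll;
* water-scaled absorption dips near 1200 and 1450 nm, a NIR plateau set by
  a structure latent;
* multiplicative (1%) then additive (0.004) Gaussian reflectance noise —
  magnitudes chosen once as typical of a well-operated field spectrometer
  at midday, since no instrument noise figure was available;
* LCC\_W = LCC\_A / SLW with SLW inversely perturbed by the water latent,
  so LCC\_W inherits water-driven scatter that LCC\_A lacks — the
  mechanism that makes the area-based trait the more estimable one;
* absorbances D663/D645 back-computed (assuming chlorophyll a:b = 3:1, a
  typical sun-leaf ratio) so the extraction formulas invert exactly, and
  latent truth stored for recovery tests.

It is a closed-form pseudo-vegetation model, not radiative transfer: no
leaf-angle or soil-background effects, no scattering physics, no
treatment/plot structure, no saturation of empirical indices at high
canopy cover. Consequently, passing tests demonstrate that the pipeline
recovers planted structure of realistic shape and magnitude — not that the
specific correlation values would reproduce on any particular field
dataset. One visible consequence: with noise off, the red-edge inflection
is exactly monotone in chlorophyll only with the other latents held fixed;
across a generated dataset the structure and water latents add about
±1 nm of position scatter, which is realistic behaviour, and the rank
correlation stays above 0.9.

## Numerical and degenerate-input conventions

* The chlorophyll-b extraction coefficients are used in the ordering
  (22.9·D645 − 4.68·D663) — the only ordering under which
  chl\_a + chl\_b ≡ chl\_total, an identity of the coefficient set that
  the total-chlorophyll equation requires. The transposed variant that
  appears in some printed method sections is kept behind `as_printed` for
  fidelity testing. The printed conversion factor is read as
  ×(V/1000)/m = 1/(40·m) at the stated 25 mL volume; dimensional analysis
  admits no other reading.
* SIPI on a constant spectrum is 0/0 and is flagged non-finite rather than
  defined away.
* Negative computed chlorophyll (physically impossible absorbance pairs)
  is flagged, not clamped.
* All stochastic stages (generation, RF, BPNN) consume explicit seeds;
  identical configuration reproduces the metrics table byte-for-byte.

## Problem sizes used in the checks

The end-to-end recovery checks run the full study geometry — 60 samples ×
1481 bands, five orders, both index kinds (≈22 million band-pair
correlations per trait) — across 20 generator seeds with the
random-forest model, which completes in a few minutes on one core thanks
to the compiled screening kernel. Unit-level oracle checks use 5–100 band
toys where brute force is exact and instant.

## Known limitations

* The generator's spectra are smooth by construction; derivative orders
  above ~1.5 mostly amplify injected noise, so (unlike on rougher field
  spectra) order 0–0.5 features often screen best on synthetic data.
* MRE divides by the observed value and is meaningless for traits that can
  approach zero; both traits here are bounded well away from zero.
* The BPNN is a small fully-connected network intended to mirror standard
  practice in this literature, not a tuned deep model.
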