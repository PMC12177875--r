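# mxraman

Multi-excitation (MX) Raman spectral barcoding and chemometrics in R.

Label-free Raman fingerprints capture the overall molecular composition of
complex biological samples, but a single laser wavelength sees a biased
slice of it: visible excitation (532 nm) preresonantly enhances
metalloprotein bands, near-infrared excitation (785 nm) emphasizes protein
backbone vibrations. `mxraman` implements the complete analysis chain for
deciding whether *fusing* configurations adds descriptive information:

* **Preprocessing** — blank subtraction, 6-level Haar-wavelet denoising
  (soft universal threshold), iterative 5th-order polynomial fluorescence
  removal (the fit is kept as the autofluorescence signal), rubberband
  (lower-convex-hull) baseline anchoring, vector normalization.
* **MX fusion** — end-on-end concatenation of per-channel fingerprints
  (532 + 785 nm, Raman + autofluorescence, self-concatenation controls) and
  depolarization-ratio spectra ρ = I⊥/I∥.
* **Spectral barcodes** — per-wavenumber two-sided Mann-Whitney U ranking,
  selection of the top-ranked *independent spectral regions* (disease
  barcodes), and universal multi-class panels of exactly 100/30/10
  variables via per-pair top-10 selection and greedy mRMR reduction
  (mutual-information difference criterion), each variable flagged as
  increased (black) or decreased (gray) in the disease class. A
  lowest-ranked ANOVA panel serves as negative control.
* **Evaluation** — first/middle/final 9:1 splits, LDA with pooled-covariance
  pseudo-inverse (p ≫ n safe) and stratified 5-fold CV, per-class
  accuracies, Kruskal-Wallis + Dunn/Bonferroni configuration comparison;
  unsupervised separation via per-class Mahalanobis spread
  mean‖Σ^{-1/2}(x−μ)‖ in the PC1–PC2 plane and averaged pairwise Gaussian
  Bhattacharyya distance
  D_B = ⅛ Δμᵀ Σ̄⁻¹ Δμ + ½ ln[det Σ̄ / √(det Σ₁ det Σ₂)].
* **Synthetic generator** — Lorentzian multi-channel spectra with
  class-specific peaks, patient-level lognormal amplitude effects, broad
  autofluorescence baselines, Gaussian noise, polarized variants, and
  ground-truth annotations for recovery tests.

Datasets are wide tibbles (one row per spectrum, metadata columns plus one
column per variable, channel/wavenumber map attached), so everything chains
with the pipe; fitted objects have broom-style `tidy()`/`glance()` methods
and `autoplot()`/`plot_spectra()` ggplot2 helpers.

## Worked example

```r
library(mxraman)

design <- default_design(n_points = 256, n_spectra = 10)  # reduced-size demo
sim    <- generate_spectra(design, seed = 1)

fp532 <- preprocess_dataset(sim$channels[["532nm"]], sim$blanks[["532nm"]])$fingerprint
fp785 <- preprocess_dataset(sim$channels[["785nm"]], sim$blanks[["785nm"]])$fingerprint
mx    <- mx_concatenate(list(fp532, fp785))
mx
#> <spectral_dataset> 150 spectra x 512 variables [raman]
#>   block 532nm: 256 variables, 600.0-1750.0 cm^-1
#>   block 785nm: 256 variables, 600.0-1750.0 cm^-1
#>   classes: control, D1, D2, D3, D4

run_protocol(list(`532` = fp532, `785` = fp785, MX = mx), seed = 1)
#> <mx_protocol> per-configuration test accuracy (mean +/- sd over class x repeat):
#>   532          37.0% +/- 20.0%
#>   785          56.3% +/- 22.4%
#>   MX           88.1% +/- 10.7%
#>   Kruskal-Wallis omnibus p = 1.34e-06 (configuration comparison, not predictive validation)
```

Fusing the two channels lifts accuracy far above either alone, because the
planted class differences are split across channels (D1 is visible only at
532 nm, D2 only at 785 nm). The accuracies are configuration comparisons on
sample-correlated splits, not predictive validation.

```r
barcode <- universal_barcode(mx, 30)
barcode
#> <mx_barcode> 'universal_30': 30 variables (19 increase / 11 decrease)
#> # A tibble: 30 x 6
#>    col_index column            channel wavenumber direction provenance
#>        <int> <chr>             <chr>        <dbl>     <int> <chr>
#>  1        90 532nm|1001.372549 532nm        1001.        -1 control_vs_D1
#>  2        33 532nm|744.3137255 532nm         744.         1 control_vs_D1
#>  3       171 532nm|1366.666667 532nm        1367.        -1 control_vs_D1
#>  ...

separation_report(mx, barcode)
#> <mx_separation> (PC space) average Bhattacharyya distance: 3.958
separation_report(mx)
#> <mx_separation> (PC space) average Bhattacharyya distance: 0.190
```

The 30-variable barcode concentrates class-descriptive variance: the
average Bhattacharyya distance between class clusters rises from 0.19
(full 512-variable MX spectrum) to 3.96, i.e. far less cluster overlap.
`autoplot(barcode)` draws the black/gray bar rendering;
`autoplot(separation_report(...))` and `autoplot(run_protocol(...))` plot
spreads and accuracy boxplots.

A command-line front end for the whole chain ships at
`system.file("cli", "mxraman", package = "mxraman")` with subcommands
`simulate`, `preprocess`, `combine`, `depolarize`, `barcode`, `metrics`,
`classify`.

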