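---
title: "Quantifying A-series gangliosides in MALDI imaging mass spectrometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying A-series gangliosides in MALDI imaging mass spectrometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gangliomsi)
```

## The measurement problem

MALDI imaging mass spectrometry (MALDI IMS) rasterizes a laser across a
thin tissue section (here: 10 μm coronal sections at 100 μm pitch, negative
reflectron mode) and records one mass spectrum per pixel. In a rat model of
focal striatal ischemia, the A-series gangliosides — GM3, GM2, GM1 and
GD1a, which differ by stepwise addition of HexNAc, Hex and NeuAc residues
onto a lactosylceramide core — redistribute inside the infarct. The
quantity of interest is not an absolute concentration (MALDI intensities
are not absolutely calibrated) but a *within-animal contrast*: the ratio of
the baseline-subtracted peak area inside the lesioned (ipsilateral) region
of interest to the area in the mirrored, non-lesioned (contralateral)
region of the same section.

This ratio design is the package's organizing principle. Tissue
heterogeneity, matrix application, and ion suppression act, to first
order, as a multiplicative factor per section; because both ROIs come from
the same section, that factor cancels exactly from the ratio. The test
suite demonstrates this cancellation property directly (a global intensity
gain changes no ratio beyond floating-point rounding).

## Ion assignment

Theoretical m/z values are computed from compositional building blocks:
monoisotopic residue masses (Hex 162.0528, HexNAc 203.0794, NeuAc
291.0954 Da), a ceramide with a d18:1 or d20:1 sphingoid base (one C₂H₄
apart, 28.0313 Da) and a fixed N-acyl chain, and the adduct arithmetic of
singly charged anions. The N-acyl chain is not resolved by the m/z
channels used here; we fix it at 18:0 (stearoyl), the dominant acyl chain
of adult mammalian brain gangliosides, and expose it as a configuration
option.

The mono-sialo species GM3, GM2 and GM1 are quantified as deprotonated
ions [M−H]⁻ (the sialic acid carboxyl being the presumed deprotonation
site). GD1a, carrying two sialic acids, is not observed as a doubly
charged anion in tissue; it appears as the two singly charged salt adducts
[M−2H+Na]⁻ and [M−2H+K]⁻, which are quantified as separate channels
(offsets +21.9819 and +37.9559 Da from [M−H]⁻). The default panel is
therefore 10 ion channels: {GM3, GM2, GM1} × {d18:1, d20:1} × [M−H]⁻ and
GD1a × {d18:1, d20:1} × {[M−2H+Na]⁻, [M−2H+K]⁻}. Electron mass is included
in the m/z arithmetic; all values are checked in the test suite against an
independently computed elemental-formula summation to 10⁻⁴ Da.

Each channel integrates a window of half-width 0.5 Da (configurable)
around the theoretical m/z. At reflectron-TOF resolution this isolates the
monoisotopic peak without reaching the +1 isotope of a neighbour; no
isotope-envelope summation is attempted. Overlapping windows are rejected
at panel-construction time with the colliding pair named.

## From pixels to one number per animal and ion

1. **ROI masking.** ROIs are polygons in 0-based pixel coordinates
   (x rightward, y downward, matching imzML pixel indices). A pixel
   belongs to an ROI when its center lies strictly inside the polygon
   under the even-odd rule. The contralateral ROI is the vertex-wise
   reflection of the ipsilateral polygon about a user-supplied sagittal
   midline (`x → 2·midline − x`); midline auto-detection is deliberately
   out of scope, since in practice ROIs are drawn manually against
   adjacent stained sections.
2. **Averaging.** The ROI's spectra are averaged bin-wise on the shared
   (continuous-mode) axis.
3. **Baseline subtraction.** The chemical baseline is estimated as a
   moving low-percentile (default: 10th percentile in a 5 Da window) of
   the averaged spectrum, smoothed once with a moving average of the same
   window, and subtracted with truncation at zero. The instrument software
   originally used for this step is unspecified in the field's workflows;
   a moving low-percentile is parameter-light and adequate for the slowly
   varying MALDI background. For speed the percentile is evaluated at
   anchor positions every k/8 bins and linearly interpolated — the
   baseline is smooth by definition, so this loses nothing measurable.
   Note one honest limitation: a low percentile sits *below* a sloped or
   noisy background by a small margin (≈0.4·window·slope on a ramp, and
   ≈1.3·σ/√(pixels) under noise), which inflates both areas additively
   and biases ratios slightly toward 1. On the shipped synthetic data this
   bias is ≈1–2% — well inside the quantification tolerances — and it
   cancels entirely in the noiseless checks.
4. **Integration.** Trapezoidal area over the ion window on the native
   axis; no peak fitting ("area under the curve" taken literally).
5. **Ratio.** `ratio = ipsi area / contra area`, one record per animal ×
   ion × timepoint. We average over the ROI first and integrate once
   (matching the depicted workflow order: average, then area); with a
   percentile-0 baseline the two orders commute exactly, and the test
   suite asserts this commutation.

Ratios, not log-ratios, are stored — the published axis is "ratio of
ipsilateral to contralateral" — but the statistics layer accepts
`log_scale = TRUE` because ratio distributions are right-skewed.

**Detection floor.** A channel whose ipsilateral or contralateral area
falls below a floor is flagged and excluded; the floor defaults to 3 × the
median absolute deviation of the baseline-subtracted contralateral
spectrum in signal-free regions (outside all panel windows ± 2 Da), scaled
by the window width. This reproduces the behaviour of weak channels that
never rise above noise in any animal — in the shipped generator, GM3
d20:1 plays this role by construction.

## Group statistics

For each ion × timepoint stratum independently, a one-way ANOVA across
surgical groups is followed by Tukey's HSD for all pairs, with α = 0.05.
No additional multiplicity correction is applied across ions; each panel
is analyzed separately, which mirrors per-panel published analyses and is
a documented limitation. The 3 d and 21 d cohorts are analyzed separately
by default (the two timepoints have different group rosters); the
cross-timepoint contrast for one group (`timecourse_test()`) is
implemented as a Tukey pair inside a single one-way ANOVA over all
group × timepoint cells — an explicit interpretive choice, since the
original cross-timepoint test is not fully specified.

Cell-count tables (Fluoro-Jade B for degenerating cells, NeuN for mature
neurons; n = 6 per cell) are summarized by
`percent_reduction = 100 × (mean₃d − mean₂₁d)/mean₃d` and analyzed with the
same ANOVA/Tukey engine.

The engine itself is `stats::aov` + `stats::TukeyHSD`; the package's tests
validate it against a 2000-draw permutation F-test and against unadjusted
pooled-SD pairwise t-tests (Tukey p must never be smaller), and verify a
5% type-I error rate over 1000 null simulations at the study's design size
(5 groups × n = 4).

## The synthetic generator

No spectral data were published for this study design, so the package
ships a generator that produces imzML spectral images with known ground
truth. Per pixel:

intensity(mz) = gain × [ baseline(mz) + Σ_ions amp_ion × fold_ion^(pixel ∈ lesion) × exp(−(mz − mz_ion)²/2σ²) ] + ε

* **Grid**: 40 × 26 pixels at 100 μm pitch — a striatal field of view; the
  lesion is an ellipse (semi-axes 5 × 6.5 px) in the left hemisphere, and
  the shipped ipsilateral ROI traces the same boundary polygon, so the
  averaged region is exactly the region carrying the fold change. (Padding
  the ROI dilutes the recovered fold by the fraction of non-lesioned
  pixels included — the partial-volume effect; `roi_margin` exposes this.)
* **Axis**: 1160–1920 Da every 0.1 Da, covering all ten channels.
* **Peaks**: Gaussian, σ = 0.15 Da (reflectron-TOF-like width),
  amplitudes 45–110 counts per ion, GM3 d20:1 at 0.4 — deliberately below
  the detection floor.
* **Baseline**: quadratic, falling 28 → 8 counts across the axis.
* **Gain**: one log-normal factor per section (sdlog 0.3), emulating
  section-to-section preparation and suppression variability.
* **Noise**: additive Gaussian, σ = 6 counts per bin (optional shot-noise
  term available), truncated at zero.
* **Effects**: the shipped fold-change table encodes the qualitative
  lesion response — GM2 up at 3 d after stroke with or without amyloid
  and persisting at 21 d only with the combined insult; GM3 d18:1 up at
  3 d only in the combined group and at 21 d also after stroke alone;
  GM1 d18:1 and GD1a[Na] d18:1 up at 3 d in the combined group; GM1 d20:1
  up at both timepoints in the combined group; GD1a[K] down at 3 d after
  stroke alone and recovered by 21 d; amyloid-alone, sham and control at
  1 everywhere. The magnitudes (1.8 up, 0.6 down) are generator defaults,
  chosen once — the underlying study reports directions and significance,
  not effect sizes.

Cell counts are negative binomial (dispersion 40, n = 6) with means chosen
so the expected FJB reduction from 3 d to 21 d is 35% in the combined
group (250 → 162.5) and 65% after stroke alone (250 → 87.5), with NeuN
equal across the two groups at 3 d and lower in the combined group at
21 d. With n = 6 the replicate-mean estimator of a ratio of means carries
a small Jensen bias (≈0.3 percentage points), visible in the acceptance
output.

**What the generator does not emulate**: anatomical texture, isotope
envelopes, peak-shape asymmetry and mass-calibration drift, spatially
structured matrix crystallization (gain is per-section, not per-pixel),
and ion-suppression chemistry. Passing the recovery tests therefore
demonstrates the correctness of the estimator under the stated noise
model, not robustness to every artifact of real acquisitions.

## Numerical and design choices

* Monoisotopic atomic masses are embedded IUPAC/CIAAW values; no network
  lookup is performed or needed.
* imzML is written in continuous mode with 64-bit floats by default
  (bit-exact round trips); the reader accepts continuous or processed
  mode and 32- or 64-bit encodings. File UUIDs are derived from an MD5
  digest of the binary payload, so output bytes are deterministic for a
  fixed input. Conformance is cross-checked in the tests against an
  independent Python imzML parser.
* Pixels exactly on a polygon edge are outside (strict even-odd rule);
  on a symmetric grid the mirrored mask then has exactly the mirrored
  membership.
* Degenerate inputs fail loudly: empty masks, overlapping ipsi/contra
  masks, windows outside the axis, baseline windows narrower than 3 bins,
  groups with fewer than two observations, unknown group labels and
  duplicated design rows are all named errors.
* Simulation sizes used in the automated checks were chosen to keep the
  full suite comfortably interactive: recovery properties use 50
  replicate sections per condition (the per-animal ratio is the unit
  estimator, so its median over replicates is the relevant recovery
  statistic), type-I error uses 1000 null ANOVA draws, and the
  significance check uses replicate full cohorts of 20 sections.

## Known limitations

* The ratio is undefined where the contralateral area is ~0; such
  channels are flagged rather than imputed.
* The low-percentile baseline slightly inflates small areas under noise
  (see above); at the shipped noise level the effect on ratios is ≈1–2%.
* Natural-scale ANOVA on ratios ignores their mild right-skew; use
  `log_scale = TRUE` when effects are large.
* Per-ion ANOVAs are not corrected across the panel.
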