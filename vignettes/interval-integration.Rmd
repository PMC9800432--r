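---
title: "Model-free interval integration of brain MR spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-free interval integration of brain MR spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrsioi)
```

## The problem

Metachromatic leukodystrophy (MLD) is a lysosomal storage disease in which
arylsulfatase-A deficiency leads to progressive demyelination of the white
matter, with a rapid late-infantile and a more protracted juvenile form.
In-vivo proton MR spectroscopy (MRS) of the brain measures metabolite
signals — N-acetylaspartate (NAA, a neuronal/axonal marker), creatine,
choline, myo-inositol, glutamine/glutamate, aspartate — per voxel, and these
change characteristically with disease severity: NAA falls, myo-inositol
and choline rise.

The classical way to quantify such spectra is basis-set fitting of single
metabolites (e.g. LCModel). `mrsioi` implements the alternative this
package is built around: a *model-free* analysis that integrates the
spectrum over ten fixed 0.08-ppm **intervals of interest** (IOIs), each
named after the metabolite dominating that spectral range, and normalizes
each integral to the interval of the main creatine peak (**Cr2**,
3.048–2.968 ppm). No lineshape model, no basis set, no fit — just
well-defined spectral areas. The cost is specificity: an interval contains
contributions from every metabolite resonating there, so results speak
about spectral regions, not pure metabolites.

```{r}
default_iois()
```

## Post-processing model

Raw input is a grid of complex free induction decays (FIDs) on the k-space
acquisition matrix of a chemical shift imaging (CSI) measurement. The
processing chain, in fixed order:

1. **Apodization.** Each FID is multiplied by $w(t) = 2^{-t/\mathrm{FWHM}}$
   with FWHM = 0.355 s, i.e. $w(0) = 1$ and the filter has decayed to one
   half at $t = \mathrm{FWHM}$. This is the only parameter-free reading of
   a time-domain "FWHM" for a monotone exponential window; the broadening
   it adds is Lorentzian with width $\ln 2 / (\pi\,\mathrm{FWHM}) \approx
   0.62$ Hz. Alternative constants can be configured.
2. **Spatial reconstruction.** The k-space matrix (default 12 × 12) is
   zero-filled symmetrically — DC sample kept centred — to the
   reconstruction matrix (default 32 × 32) and inverse-Fourier-transformed
   per time point. The pipeline evaluates this transform only at the
   region-of-interest voxels via an explicit DFT, which is exactly equal to
   the full zero-filled FFT there (the padded entries are zero); the
   equality is proven in the test suite.
3. **Fourier transform** of each voxel FID, with the frequency axis mapped
   to chemical shift by $\mathrm{ppm} = \mathrm{carrier} +
   f/f_\mathrm{transmitter}$ and returned in decreasing-ppm convention.
4. **Frequency correction.** The NAA peak is located as the maximum of the
   real part inside a search window (default 1.75–2.25 ppm) and the whole
   spectrum is shifted so the peak lands on 2 ppm. The default shift is a
   circular rotation by the nearest whole number of spectral bins — the
   axis itself is never altered — because the measured displacement is only
   known to bin precision anyway; sub-bin linear interpolation is available
   as an option. No phase correction is applied by default; a zero-order
   phase step exists for user data.
5. **Baseline subtraction.** The baseline offset is estimated as the mean
   real intensity between 0.9 and 1.6 ppm — a range without major
   metabolite peaks — and subtracted, so that window has exactly zero mean
   afterwards.

Each interval integral is then the absolute value of the trapezoidal
integral of the real part over the axis points falling inside the closed
interval, at native axis resolution (no resampling, no partial-bin
weights). Integrating the real part (rather than the magnitude) keeps the
operation linear in metabolite amplitude and robust to small negative
lobes; a magnitude mode exists as an option.

Voxels are grouped into five ROIs; ROI means are combined into regions:
FWM = mean(ROI 1, 2) (frontal white matter, left/right), CST = mean(ROI 3,
4) (corticospinal tract), WM = mean(ROI 1–4), GM = ROI 5. Averaging ratios
over ROIs — rather than averaging spectra and then integrating — is the
default because the Cr2-normalized ratio is the analysis unit; averaging
spectra first is available through `average_spectra()` for group-mean
displays.

## Spectral axis defaults

The ratio results are insensitive to the absolute frequency axis, but the
simulator and the ppm mapping need concrete values. The defaults — dwell
time 1/1200 s (spectral width 1200 Hz), transmitter 123.25 MHz, carrier
4.7 ppm — are typical 3 T proton values and are plain configuration
(`acq_config()`). With 1024 points they give a spectral resolution of
about 0.0095 ppm, i.e. roughly 8 axis points per 0.08-ppm interval.

## The synthetic cohort generator

No patient data ship with the package; `simulate_cohort()` +
`simulate_fid()` generate data with the statistical structure the analysis
assumes, with known ground truth:

* **Forward model.** Each voxel FID is a sum of exponentially damped
  complex sinusoids (Lorentzian lines, default width 4 Hz), one line per
  interval at the interval midpoint, scaled by per-subject amplitude
  multipliers. A global frequency shift (default uniform in ±0.1 ppm) and
  a baseline offset are injected per scan, plus i.i.d. complex Gaussian
  noise per spatial voxel and time point. The baseline offset is defined
  as a frequency-domain constant; by the DFT's unit-impulse pair this is
  realized by adding the constant to the first time-domain sample — the
  two are the same object under the discrete transform.
* **Cohorts.** Defaults mirror a 12 control / 19 juvenile / 10
  late-infantile cohort. Patients draw a severity scale (mean 1, sd 0.35)
  multiplying log-scale group effects: myo-inositol and choline intervals
  up (×1.3 juvenile, ×1.6 late-infantile), the others down, most strongly
  NAA2 (×0.75, ×0.50); Cr2 is held at 1 so the normalization denominator is
  stable by construction. Controls carry no disease effect.
* **Clinical covariates.** The motor score (GMFC-MLD, integers 0–6) is a
  thresholded linear map of a latent Gaussian coupled to the subject's NAA
  amplitude at the level $\rho = 2\sin(\pi\rho_s/6)$ that yields the target
  Spearman correlation (−0.75 by default) for bivariate normal data;
  rounding to seven levels and pinning controls at 0 attenuate this
  somewhat, which is why recovery is asserted within a ±0.15 band rather
  than exactly. IQ is a linear function of NAA amplitude with noise set to
  the target Pearson correlation (+0.84), standardized within the subset
  where IQ is observed (controls and juvenile patients; late-infantile
  patients are below testable age), centred at 92 ± 12 so both IQ ≥ 85
  classes are populated; half the juvenile scans keep only the binary
  IQ ≥ 85 indicator, mimicking incomplete psychometric data. The urinary
  NAA/creatinine ratio is $\exp$ of a latent coupled negatively to brain
  NAA (target Spearman −0.55, patients only) — the monotone transform
  leaves rank correlations untouched while keeping the ratio positive.

What the generator does **not** emulate: J-coupled multiplets,
macromolecule baselines, B0 field maps, spatially varying anatomy,
scanner drift, or partial-volume effects. Passing tests therefore show
that the *pipeline* recovers what it assumes from data obeying its own
forward model — they say nothing about contamination between overlapping
metabolites in real spectra, which is the documented, accepted limitation
of interval integration.

## Statistics layer

Group differences use one-way ANOVA with Tukey–Kramer post-hoc pairs
(valid for unequal group sizes); ratios with zero variance (the Cr2 ratio
is identically 1) short-circuit to F = 0, p = 1. Correlations follow the
measurement scale: Spearman with average ranks for the ordinal GMFC-MLD
(exact permutation p for n ≤ 9, t approximation otherwise), Pearson for
continuous IQ, Spearman with the IQ ≥ 85 indicator coded 1/0. The marker
threshold analysis dichotomizes a ratio (default NAA2 in FWM at 1.5)
against the binary outcome and reports the cross-product odds ratio, with
the Haldane–Anscombe +0.5 correction whenever a cell is empty (flagged in
the output). Method agreement uses Bland–Altman limits
$\bar d \pm 1.96\,s_d$ and the coefficient of variation is defined as
sd/mean — reported variation figures on the order of 0.1–0.2 only make
sense on that reading.

Missing clinical values are handled by pairwise deletion, with n reported
per result. Repeated scans enter as independent observations by default;
`analysis_options(independent_only = TRUE)` keeps only each subject's most
recent scan as a sensitivity analysis. No multiple-testing correction is
applied by default (significance is unadjusted p < 0.05); a
Benjamini–Hochberg option exists.

## Numerical and design choices

* **NAA search window vs. shift range.** A search window must bracket the
  largest plausible shift: the default (1.75–2.25 ppm) detects shifts up to
  ±0.25 ppm. Simulations that inject shifts up to ±0.3 ppm therefore pass
  a wider window (1.65–2.35 ppm) explicitly; with the default basis the
  NAA2 line dominates everything else that can enter that window.
* **Degenerate inputs.** A flat (e.g. all-zero) search window yields shift
  0 with a `flat_window` flag and a warning rather than an error, so empty
  voxels pass through as empty spectra. Spectra whose Cr2 integral is not
  positive are rejected as unusable. Bland–Altman with all-zero
  differences counts points lying on the collapsed limits as within.
* **Ties and boundaries.** Interval membership is closed on both ends;
  rank ties use average ranks; the odds-ratio dichotomy is `value >=
  threshold`.
* **Seeds.** Every stochastic operation takes an explicit seed
  (`simulation_truth()`, `cohort_params()`); per-scan seeds are derived
  from the cohort seed, and nothing touches the caller's RNG state.
  Identical configuration + seed reproduces outputs byte-for-byte.
* **Problem sizes.** The test suite validates shift recovery on 200
  spectra, the ANOVA's type-I error on 2000 null replicates (n = 10 per
  group), and effect-size recovery on 100 cohorts of n = 60 scans run
  through the complete FID-to-statistics pipeline — sizes chosen so the
  whole suite completes in minutes on a single core while keeping
  Monte-Carlo error well below the asserted tolerances.

## Limitations

Interval integrals are not metabolite concentrations: overlapping
resonances contribute to every interval, there is no absolute
(institutional-unit) scaling, no eddy-current or coil-combination steps,
and the lactate region is outside the default interval set. The package
deliberately does not implement basis-set fitting; where a fitted
reference is available, `bland_altman()` and `coefficient_of_variation()`
quantify how the two approaches agree.
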