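# mrsioi

Model-free interval-of-interest analysis of brain proton MR spectroscopy,
aimed at leukodystrophy cohorts — in particular metachromatic
leukodystrophy (MLD), where white-matter metabolite changes (falling
N-acetylaspartate, rising myo-inositol and choline) track motor and
cognitive decline.

## Who this is for

Researchers who have chemical shift imaging (CSI) free-induction-decay
data and want a quantification that needs **no metabolite basis set and no
fitting**: instead of modelling single metabolites, the spectrum is
integrated over ten fixed 0.08-ppm intervals of interest (IOIs), each
named after the metabolite dominating that range, and every integral is
normalized to the main creatine interval (Cr2, 3.048–2.968 ppm). The
resulting ratios are compared between cohorts and correlated with
clinical scores. A full synthetic-cohort simulator with known ground
truth is included for validation and power analysis.

## The method

For every voxel FID \(s(t)\):

1. apodization with the exponential filter \(w(t) = 2^{-t/0.355\,\mathrm{s}}\);
2. zero-filled spatial reconstruction of the CSI k-space grid
   (12 × 12 → 32 × 32 by default);
3. Fourier transform to a spectrum \(S(\mathrm{ppm})\) on a decreasing
   ppm axis;
4. frequency alignment: the NAA peak is located near 2 ppm and the
   spectrum is shifted (whole spectral bins) so it sits exactly there;
5. baseline correction: the mean real intensity over 0.9–1.6 ppm is
   subtracted.

Then, for each interval \([p_\mathrm{low}, p_\mathrm{high}]\) of the ten
IOIs (Myo1, Cr1, Glx, Myo2, Cho, Cr2, Asp, NAA1, Gln, NAA2),

\[
A_k = \left|\int_{p_\mathrm{low}}^{p_\mathrm{high}} \Re\,S(p)\,dp\right|,
\qquad r_k = A_k / A_{\mathrm{Cr2}},
\]

computed by the trapezoidal rule on the native axis. Five ROI voxels are
aggregated into regions — FWM (frontal white matter, ROIs 1–2), CST
(corticospinal tract, ROIs 3–4), WM (ROIs 1–4), GM (ROI 5) — and the
statistics layer runs one-way ANOVA with Tukey post-hoc tests between
cohorts, Spearman correlation with the ordinal GMFC-MLD motor score
(0–6), Pearson correlation with IQ, a threshold odds ratio (NAA2 in FWM
at 1.5 vs IQ ≥ 85), Spearman correlation with urinary NAA/creatinine,
and Bland–Altman / coefficient-of-variation method comparison.

## Worked example

Simulate the default synthetic cohort (12 controls, 19 juvenile, 10
late-infantile subjects), push every scan through the FID → spectrum →
ratio pipeline, and run the clinical statistics:

```r
library(mrsioi)

cfg <- default_run_config()
cfg$seed <- 1L
res <- run_pipeline(cfg)

subset(res$results$correlations, ioi == "NAA2" | analysis == "urine_gmfc")
#>    analysis  ioi region   method estimate        p  n significant
#>        gmfc NAA2    CST spearman   -0.785 1.25e-09 41        TRUE
#>          iq NAA2    FWM  pearson    0.779 1.97e-05 22        TRUE
#>    iq_ge_85 NAA2    FWM spearman    0.649 4.44e-06 41        TRUE
#>       urine NAA2     WM spearman   -0.639 1.91e-04 29        TRUE
#>  urine_gmfc <NA>   <NA> spearman    0.497 6.06e-03 29        TRUE

res$results$odds_ratio
#>   ioi region threshold odds_ratio  a b c  d corrected  n
#>  NAA2    FWM       1.5      53.33 20 3 2 16     FALSE 41
```

Reading the output: across 41 scans, the NAA2 ratio in the corticospinal
tract falls as motor impairment rises (Spearman rs = −0.79), the NAA2
ratio in frontal white matter rises with IQ (Pearson r = 0.78 over the 22
scans with an absolute IQ), brain NAA2 is negatively related to urinary
NAA/creatinine (rs = −0.64), and an NAA2/Cr2 ratio of 1.5 in frontal
white matter separates IQ ≥ 85 from IQ < 85 with an odds ratio of 53 —
the synthetic cohort was generated with exactly this kind of structure,
so the pipeline is recovering the associations it was given. Group
comparisons live in `res$results$group_comparisons`, the per-scan ratios
in `res$ratio_table` (Cr2 is 1 everywhere by construction).

A shell interface wrapping the same functions is installed at
`inst/cli/mrsioi` (subcommands `simulate`, `process`, `integrate`,
`analyze`, `all`).

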