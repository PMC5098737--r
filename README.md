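# renalmr

Multiparametric functional MRI quantification of renal allograft
rejection, for imaging scientists and transplant researchers working with
small-animal (or, with adjusted protocols, human) kidney data.

Acute rejection raises graft cellularity (leukocyte infiltration) and
damages the microvasculature (intimal arteritis). Both leave quantitative
MR signatures, and `renalmr` implements the full chain from image series
to group statistics:

* **Diffusion.** Monoexponential ADC mapping,
  `S(b) = S0·exp(−b·ADC)`, fitted by weighted log-linear least squares
  over a ten-b-value protocol (0–800 s/mm²), and a *segmented* IVIM
  analysis of the biexponential model
  `M(b) = M0·(fp·e^(−b·Dp) + (1−fp)·e^(−b·Dt))`:
  tissue diffusivity `Dt` and intercept `Mint = M0(1−fp)` from the
  b > 200 s/mm² asymptote, perfusion fraction `fp = (M0 − Mint)/M0` from
  the measured b = 0 signal, pseudo-diffusivity `Dp` from a bounded
  one-parameter refit.
* **Perfusion.** Model-free deconvolution of DCE series against an
  arterial input function by truncated SVD of the convolution system
  `A·h = c`. Plasma flow `FP = max(h)` (ml/100ml/min), extracellular
  volume `ECV = ∫h` (ml/100ml), mean transit time `MTT = ECV/FP` (min,
  exact identity).
* **Statistics.** Pooled unpaired two-tailed t-tests (also from published
  summary statistics alone), Lilliefors/Kolmogorov–Smirnov normality
  screening, Pearson/Spearman correlation of MR metrics against ordinal
  histology scores and F4/80+ macrophage infiltration, Bonferroni
  correction.
* **Synthetic data.** Digital kidney phantoms, Rician-noise DWI,
  bolus-passage DCE with a gamma-variate AIF, and a calibrated
  latent-factor cohort simulator reproducing a five-group (n = 5)
  transplant study layout with known ground truth — so the entire
  pipeline is testable without scanner data.

## Worked example

```r
library(renalmr)

# --- a rejecting graft: forward-simulate, then quantify -------------------
p  <- make_protocol(dwi_shape = c(10, 10, 1), dce_shape = c(10, 10, 1))
ph <- make_phantom(p, graft = list(dt = 0.63e-3, fp = 0.12, dp = 10e-3,
                                   fp_dce = 23.48, ecv = 30))

roi_summary(fit_adc(simulate_dwi(ph), mask = ph$kidney_mask),
            ph$kidney_mask, "graft")
#>   metric   mean sd n_voxels          unit   roi
#> 1    adc 0.8075  0       14 mm^2/s x10^-3 graft

fit_dce(simulate_dce(ph), mask = ph$kidney_mask,
        aif_mask = ph$artery_mask, reg = 1e-6)$result
#> Plasma flow 23.48 ml/100ml/min, ECV 29.95 ml/100ml, MTT 1.276 min
```

The ROI ADC (0.81 × 10⁻³ mm²/s) sits *above* the generating tissue
diffusivity (0.63 × 10⁻³) because the monoexponential fit absorbs the
12 % capillary pseudo-diffusion pool — the expected physics, and the
reason the IVIM decomposition exists. The deconvolved plasma flow returns
the generating 23.48 ml/100ml/min exactly on noiseless data, and
MTT·FP = ECV holds to machine precision.

```r
# --- group statistics on published-style summaries and a synthetic cohort --
bonferroni(ttest_summary(1.29, 0.12, 5, 0.63, 0.08, 5, metric = "adc",
                         group_a = "syngeneic", group_b = "revmNOX-E36"),
           m = 8)
#> adc: syngeneic (1.29±0.12, n=5) vs revmNOX-E36 (0.63±0.08, n=5)
#>   t = 10.233, df = 8, p = 7.15e-06 (adjusted 5.72e-05, m = 8) *

cohort <- simulate_cohort(seed = 1)   # 25 animals, 5 groups
correlate(cohort, "adc", "f480_pct", method = "pearson")
#> adc vs f480_pct: pearson r = -0.811 (p = 8.96e-07, n = 25)
correlate(cohort, "plasma_flow", "intimal_arteritis")  # auto -> Spearman
#> plasma_flow vs intimal_arteritis: spearman r = -0.651 (p = 0.000422, n = 25)
```

The severely rejecting untreated group differs from syngeneic controls at
p < 0.001 even after correcting for eight tests, and the simulated cohort
reproduces the strong negative ADC–macrophage and perfusion–arteritis
correlations it was calibrated to.

`run_pipeline(list(seed = 1, out_dir = "out"))` chains
simulate → fit-dwi → fit-dce → stats and writes `report.json`, the cohort
CSV and (optionally) NIfTI maps and PNG renderings;
`inst/scripts/renalmr` exposes the same stages as a command line
(`simulate`, `fit-dwi`, `fit-dce`, `stats`, `run`).

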