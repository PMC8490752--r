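# tracefit

Multiparametric modelling of fast, multi-b-value **trace diffusion MRI** of
the brain: joint estimation of perfusion and diffusion microstructure from a
single four-minute acquisition.

A trace (direction-averaged) diffusion protocol sampling 16 b-values from 0
to 3000 s/mm² probes three water-mobility regimes at once: pseudo-perfusion
(intravoxel incoherent motion, IVIM, at b ≲ 200 s/mm²), Gaussian tissue
diffusion, and non-Gaussian (kurtosis) diffusion at high b. `tracefit`
implements the four nested signal representations

```
mono:      S(b)/S(0) = exp(-b·D_app)
IVIM:      S(b)/S(0) = f·exp(-b·D*) + (1-f)·exp(-b·D_app)
kurtosis:  S(b)/S(0) = exp(-b·D_app + (1/6)·b²·D_app²·K_app)
combined:  S(b)/S(0) = f·exp(-b·D*) + (1-f)·exp(-b·D_app + (1/6)·b²·D_app²·K_app)
```

and estimates the perfusion fraction `f`, pseudo-diffusion coefficient `D*`
(mm²/s), apparent diffusivity `D_app` (mm²/s) and apparent kurtosis `K_app`
— plus the blood-flow surrogate `f·D*` — with two constrained routines:

* a **sequential (segmented) fit**: log-linear slope over b ∈ [500, 1000]
  for `D_app`, intercept deficit for `f`, bounded 1-D search for `D*` on
  b ≤ 200, and an amplitude-corrected kurtosis refit on b ≥ 1000;
* a **simultaneous fit**: all four parameters jointly, by Nelder–Mead on
  logit-transformed coordinates so the box constraints
  (f ∈ [0, 0.3], D* ∈ [0.004, 0.05], D_app ∈ [0.0001, 0.003], K_app ∈ [0, 3])
  hold exactly.

Fits run per voxel, on in-slice 3×3 neighbourhood-averaged signal, or on
ROI-averaged signal with AICc/RMSE model comparison across the four nested
models. Around the fitters the package provides the supporting pipeline —
PCA denoising with a Marchenko–Pastur threshold, noise-floor subtraction
from image corners, Gaussian smoothing (FWHM 1.5 voxels, 3×3×3), NIfTI +
FSL-`.bval` I/O — a digital tissue-class phantom with the published
grey-matter/white-matter/oedema/tumour parameter sets and mask overlap-
resolution rules, and a Monte-Carlo recovery engine that quantifies the
accuracy and precision of every estimator as a function of SNR.

Intended users: researchers in quantitative diffusion MRI and image-analysis
methodologists who need a reference implementation of combined
IVIM/kurtosis fitting with a validated simulation harness.

## Worked example

Fit one noisy grey-matter decay and compare models on a 1024-voxel phantom
ROI:

```r
library(tracefit)

gm <- diffusion_params(f = 0.13, d_star = 8.43e-3, d_app = 1.12e-3, k_app = 0.83)
scheme <- trace_scheme()                      # 16 b-values, 0..3000 s/mm^2
set.seed(42)
noisy <- signal_decay(scheme, add_noise(predict_signal("full", gm, scheme),
                                        noise_spec(50)))   # b=0 SNR 50
fit <- fit_simultaneous(noisy)
fit
#> <dwi_fit> simultaneous fit of the full model (16 points)
#>   f = 0.1455  D* = 0.01272  D_app = 0.001057  K_app = 0.8185  (f.D* = 0.001851)
#>   RSS = 0.004944 over 16 b-values
```

At single-voxel SNR 50 the Gaussian-regime parameters come back close to
truth (`D_app` 1.06e-3 vs 1.12e-3, `K_app` 0.82 vs 0.83) while the IVIM
parameters scatter more (`D*` 0.0127 vs 0.0084) — the quantitative reason
the package (and practice) fits `f` and `D*` on neighbourhood- or
ROI-averaged signal. On a phantom grey-matter ROI the combined model wins
the corrected-AIC comparison:

```r
ph <- generate_phantom(phantom_config(snr = 50), seed = 1)
rf <- fit_roi(ph$dwi, ph$masks$gm)            # mean signal over 1024 voxels
rank_models(tidy(rf))
#> # A tibble: 5 × 7
#>    rank model_id               rss     n     k     rmse   aicc
#>   <int> <chr>                <dbl> <int> <int>    <dbl>  <dbl>
#> 1     1 full            0.00000522    16     4 0.000571 -227.
#> 2     2 kurtosis        0.00614       16     2 0.0196   -121.
#> 3     3 ivim            0.00604       16     3 0.0194   -118.
#> 4     4 full_sequential 0.00924       16     4 0.0240   -108.
#> 5     5 mono            0.0666        16     1 0.0645    -85.4
```

Lower AICc is better: both the IVIM term and the kurtosis term earn their
parameters once the averaged signal is clean enough to distinguish the
models. `run_recovery_study()` repeats such fits over thousands of noise
draws and tabulates mean, SD, coefficient of variation, bias and relative
error per parameter, SNR level and fitter; `autoplot()` charts the result.

A thin command-line wrapper over the same functions ships in
`inst/cli/tracefit.R` (subcommands `fit`, `denoise`, `simulate`, `phantom`,
`compare-models`, `correlate`, `masks`).

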