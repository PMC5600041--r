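# BayesTmax

Tmax is the de-facto imaging metric for delineating the ischemic penumbra
in acute stroke: the time of the peak of the flow-scaled tissue residue
function k(t) = CBF·R(t) recovered by SVD deconvolution of bolus-tracking
perfusion data. Bayesian tracer-kinetic estimators are more robust than
the SVD family at low SNR, but they return physiological parameters — the
tracer arrival delay TD, the mean transit time MTT, and CBF — and no Tmax,
because Tmax is an artifact of the SVD residue reconstruction rather than
a physiological quantity.

**BayesTmax** computes a Tmax surrogate from Bayesian estimates through
the calibrated linear relation

    Tmax(Bayesian) = TD + p · MTT + q

where the constants (p, q) are fitted by linear least squares against a
reference Tmax map (block-circulant SVD by default; any external Tmax map
with matching geometry is accepted, so one Bayesian parameter set can
emulate the Tmax convention of any SVD package). Everything needed to
validate the relation at desk scale is included:

* `buildPhantom()` — a digital perfusion phantom with full ground truth:
  7 TD levels × 7 MTT levels of square tiles per slice, 5 CBV levels × 3
  residue shapes (exponential, linear, box) across 15 tissue slices, a
  16th slice carrying the global AIF/VOF, 2-s sampling over 60 s, seeded
  CT-like Gaussian noise;
* `svdDeconvolve()` / `deconvolveVolume()` — sSVD, block-circulant bSVD
  and oscillation-index-regularized oSVD deconvolution with CBF/CBV/MTT/
  Tmax map extraction;
* `bayesFitCurve()` / `bayesFitVolume()` — an amplitude-profiled,
  noise-marginalized grid posterior over (TD, MTT, residue shape);
* `fitPQ()` / `applyPQ()` / `calibrateTmax()` — the (p, q) calibration;
* `pearsonR()`, `linReg()`, `iccAbsolute()` (ICC(2,1), two-way random
  effects, absolute agreement, single measures), `agreementReport()`;
* `runExperiment()` — the full pipeline with NIfTI/CSV/JSON artifacts,
  plus a thin command-line front end in `exec/bayestmax`.

## Worked example

```r
library(BayesTmax)
res <- runExperiment(runConfig(seed = 42L))
res$fit
#> CalibrationFit vs bsvd: Tmax = TD + 0.3602 * MTT + 1.18
#>   n = 735 (0 excluded), rms residual = 0.8373 s
res$reports$tmax
#> AgreementReport: tmax_bsvd vs tmax_bayesian (n = 735)
#>   r = 0.9529; y = 0.9110 x + 0.5237; ICC(2,1) = 0.9520
res$reports$td
#> AgreementReport: td_true vs td_bayesian (n = 735)
#>   r = 0.9613; y = 0.9650 x + 0.1142; ICC(2,1) = 0.9595
res$reports$mtt
#> AgreementReport: mtt_true vs mtt_bayesian (n = 735)
#>   r = 0.9920; y = 1.0113 x + -0.2531; ICC(2,1) = 0.9915
```

Reading: on the default seeded phantom the least-squares calibration
against bSVD Tmax returns p ≈ 0.36 (each second of MTT adds ≈0.36 s of
Tmax) and q ≈ 1.2 s; the calibrated Bayesian Tmax then agrees with the
bSVD reference with r = ICC ≈ 0.95 over all 735 tile ROIs, while the
Bayesian TD and MTT estimates track the ground truth with r ≈ 0.96 and
0.99. The per-curve estimator is available directly:

```r
aif <- gammaVariateAif(makeTimeGrid(2, 60))
ct  <- synthesizeTissueCurve(aif, td = 2, mtt = 8, cbv = 3,
                             shape = "exponential")
bayesFitCurve(ct, aif)
#> BayesEstimate: TD = 2 s, MTT = 7.98 s, CBF = 22.54 mL/100g/min
#>   shape = exponential, rss = 0.0002687
```

The methods vignette
(`vignettes/tmax-from-bayesian-deconvolution.Rmd`) documents the model,
the phantom design (AIF waveform, noise calibration, discretization), the
Tmax peak-localisation choice, and known limitations.

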