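# nirsflow

Event-related functional near-infrared spectroscopy (fNIRS) analysis in R:
from raw dual-wavelength detector intensities to hemoglobin responses, ROI
group statistics, and regularized cortical maps — with a ground-truth
forward simulator so the whole chain is verifiable end to end.

## Who this is for

Researchers analyzing event-related continuous-wave fNIRS of motor and
motor-related cortex — for example task designs contrasting the execution
and observation of hand actions of differing motor complexity — who want a
scriptable, reproducible, *testable* pipeline rather than a GUI toolbox.
Every stage is an ordinary function that takes and returns tidy-friendly
objects (`tidy()`, `glance()`, `autoplot()` methods throughout).

## The pipeline

1. **Optical density**: `OD(t) = -ln(I(t) / mean I)` per channel and
   wavelength, with channel pruning outside the 80–140 dB range
   (`intensity_to_od()`, `prune_channels()`).
2. **Motion correction**: hybrid spline + Savitzky–Golay scheme — sliding
   amplitude-change detection, spline subtraction with segment
   re-leveling, SG smoothing of corrected channels (`correct_motion()`).
3. **Band-pass**: zero-phase Butterworth, 0.01–0.5 Hz, effective order 6
   (`bandpass_filter()`).
4. **Modified Beer–Lambert law** with partial pathlength factor 6 and the
   standard 690/830 nm hemoglobin extinction coefficients (`mbll()`):

   `[ΔOD_690, ΔOD_830]ᵀ = L · ppf · E · [ΔHbO, ΔHbR]ᵀ`

5. **HRF deconvolution**: OLS GLM with 18 unit-peak Gaussian basis
   functions (σ = 1 s, means −2…15 s), per-run polynomial drifts, and the
   best-correlated short-separation channel as a simultaneous physiology
   regressor; baseline-corrected over −2…0 s (`fit_hrf_glm()`).
6. **Group statistics**: ROI averaging (six ROIs per hemisphere), windowed
   mean-peak paired t tests with Shapiro–Francia checks and
   Benjamini–Hochberg FDR (0.05) per hemisphere, pointwise 95% confidence
   bands, and time-to-peak summaries (`run_contrasts()`,
   `temporal_summary()`, `confidence_band()`).
7. **Image reconstruction**: minimum-norm Tikhonov inverse
   `X = Aᵀ(AAᵀ + λI)⁻¹y`, λ = 0.01, over the baseline window and every 3 s
   post-onset (`build_toy_sensitivity()`, `reconstruct_map()`,
   `window_maps()`).

The simulator (`default_probe()`, `design_spec()`, `generate_schedule()`,
`truth_params()`, `simulate_subject()`) generates the full study design —
a 60-channel bilateral probe (52 long + 8 short channels), 350 s runs of
35 pseudo-randomized trials over five conditions — with condition-locked
two-gamma responses, systemic physiology, superficial contamination,
motion artifacts and measurement noise, all recorded as ground truth.

## Worked example

```r
library(nirsflow)

study <- run_study(study_config(seed = 42))
study
#> <nirs_study> 21 subjects, seed 42, config 8ff7bbbf
#> significant ROI contrasts (FDR-corrected):
#>   exec_complex_vs_simple: M1 (left)  t(20) = 7.35, q = 0.0000
#>   exec_complex_vs_simple: IFG/PMv (right)  t(20) = 7.57, q = 0.0000
#>   exec_complex_vs_simple: M1 (right)  t(20) = 7.58, q = 0.0000
#>   exec_complex_vs_simple: IPL/SMG (right)  t(20) = 7.26, q = 0.0000
#>   exec_complex_vs_simple: MOG (right)  t(20) = 8.11, q = 0.0000
#>   obs_complex_vs_control: M1 (left)  t(20) = 6.99, q = 0.0000
#>   obs_complex_vs_control: IFG/PMv (right)  t(20) = 7.82, q = 0.0000
#>   obs_complex_vs_control: M1 (right)  t(20) = 7.95, q = 0.0000
#>   obs_complex_vs_simple: M1 (left)  t(20) = 5.91, q = 0.0001
#>   obs_complex_vs_simple: IFG/PMv (right)  t(20) = 6.82, q = 0.0000
#>   obs_complex_vs_simple: M1 (right)  t(20) = 6.00, q = 0.0000
```

The report lists, per contrast, the ROIs whose windowed mean-peak HbO
difference survives FDR correction. The default configuration injects
complexity effects into right IFG/PMv plus bilateral M1 for observation,
and additionally right IPL/SMG and right MOG for execution — exactly the
sets the pipeline recovers above. The time-to-peak summary shows the two
response regimes the simulator encodes (slow observation responses, fast
execution responses with a delayed HbR trough):

```r
study$temporal$summary
#>         class chromophore mean_ttp    sd_ttp  n
#>     execution         hbo 5.718095 0.2282021 21
#>     execution         hbr 8.683810 0.3266569 21
#>   observation         hbo 9.714286 0.6566930 21
#>   observation         hbr 9.864762 0.8195097 21
```

`study$contrasts` is a tidy tibble (one row per contrast × ROI with
`t`, `df`, `p`, `q`, normality statistics); `autoplot(study$roi_hrf)`
draws group HRFs with pointwise 95% confidence bands per ROI;
`write_results(study, dir)` writes everything as CSV with a provenance
hash.

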