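---
title: "nirsflow: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{nirsflow: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirsflow)
```

nirsflow implements a complete event-related fNIRS analysis chain - raw
dual-wavelength intensity to hemoglobin concentration changes, deconvolved
hemodynamic response functions (HRFs), region-of-interest (ROI) group
statistics, and regularized cortical maps - together with a forward
simulator whose ground truth makes every stage testable. This vignette
explains the models, the defaults and why they were chosen, the numerical
decisions, and what passing the package's tests does and does not show
about real recordings.

## The measurement model

A continuous-wave instrument records detector intensities $I_\lambda(t)$ at
690 and 830 nm at 25 Hz over a probe of 16 sources and 32 detectors. Pairs
separated by 2.5-3.5 cm ("long" channels, 52 of them) interrogate cortex;
pairs at 0.6-1.0 cm ("short" channels, 8) see only scalp. Optical density
change is defined against the within-run mean,

$$\Delta OD_\lambda(t) = -\ln\frac{I_\lambda(t)}{\bar I_\lambda},$$

so concentration changes are identified only up to an additive per-channel
constant; every comparison against ground truth aligns that reference by
mean-centering. The modified Beer-Lambert law maps OD to chromophore
changes through the 2x2 extinction matrix $E$ (natural-log units; the
packaged table is the standard compiled hemoglobin spectrum at the two
wavelengths), a source-detector separation $L$, and a partial pathlength
factor (ppf) of 6:

$$\begin{pmatrix}\Delta OD_{690}\\ \Delta OD_{830}\end{pmatrix}
 = L \cdot \mathrm{ppf} \cdot E
 \begin{pmatrix}\Delta HbO\\ \Delta HbR\end{pmatrix}.$$

The ppf is a wavelength-independent scalar here; it rescales amplitudes
uniformly and cancels exactly in forward/inverse round trips.

## Preprocessing

**Pruning.** Channels whose mean intensity falls outside 80-140 dB
(`20 log10` of the instrument unit) are excluded: below the floor the
signal-to-noise ratio is inadequate, above it the detector saturates. The
mean level (not minimum or maximum) is used; the dB reference is the raw
instrument unit, so users of other systems must rescale accordingly.

**Motion correction** is the hybrid spline + Savitzky-Golay scheme.
Detection uses the difference of adjacent 0.5 s means of a 1 s moving
average. The 1 s averaging window cancels cardiac pulsation (a full period
at typical heart rates) and measurement noise, so fast instrumental
transients - spikes and baseline steps - tower over the statistic while
hemodynamic and slow physiological transitions stay small. A window is
flagged when the statistic exceeds both 8x the channel's robust per-sample
noise SD (artifacts are, by their physical origin, many noise SDs tall)
and 8x a median + 1.48 MAD floor of the statistic itself (which keeps
noise-free data untouched). These thresholds were calibrated once on
synthetic clean versus artifact-bearing scans: injected artifacts sit
10-25x above the combined floor, the steepest hemodynamic transitions
below 6x. Flagged runs are dilated by 1 s, fit with a natural cubic spline
through 0.25 s local means (capturing the artifact trajectory while
averaging out noise), the spline is subtracted, the segment re-leveled to
the preceding 0.5 s of signal, and everything after the segment shifted to
remove any residual step - so a baseline jump is corrected globally, not
just inside the mask. The Savitzky-Golay stage (3 s window, cubic) then
smooths residual transients - only on channels that were actually
corrected. Untouched channels pass through bit-identical; their broadband
noise is the band-pass filter's job, and this choice is what makes "clean
data pass through nearly unchanged" literally true.

**Band-pass filtering** uses the order-3 Butterworth band-pass design at
0.01-0.5 Hz applied with exactly zero phase, i.e. the forward-backward
magnitude response of effective order 6. Zero phase matters because peak
*timing* is an endpoint of the analysis. The response is applied in the
frequency domain on mirror-extended series, which filters all channels in
one batch and avoids edge transients; `signal::filtfilt` is the
equivalence oracle in the test suite. Filtering precedes the Beer-Lambert
conversion, matching the stated order of operations (motion correction,
then filtering, then conversion).

**Resampling.** After motion correction (which needs the native 25 Hz to
see fast transients) the series may be block-mean decimated to an analysis
rate of 5 Hz. The retained 0.01-0.5 Hz band is 10x oversampled at 5 Hz, and
the GLM design matrix is decimated by the *identical* block means, so the
decimated regression model is exact, not an approximation - noiseless
recovery through the 5 Hz path matches the 25 Hz path to 6 decimal places
in the tests. The estimated HRFs are still evaluated on the native-rate
lag grid.

## HRF deconvolution

Each long channel and chromophore is modeled by ordinary least squares:

$$y(t) = \sum_{c}\sum_{k} \beta_{ck}\, g_k(t - \text{onsets}_c)
       + \text{drift}(t) + \gamma\, s(t) + \varepsilon(t),$$

with $g_k$ eighteen unit-peak Gaussian bumps ($\sigma$ = 1 s, means 1 s
apart from -2 to 15 s), per-run Legendre drift polynomials, and $s(t)$ the
short-separation channel most correlated with that long channel. Choices
where the conventions genuinely vary:

* **Drift order 3 per run.** Very-low-frequency drift surviving the
  high-pass corner is absorbed per run; the order is configurable.
* **Short-channel selection** uses the *signed* maximum Pearson
  correlation (not the absolute value), computed on the band-passed
  concentration series, per chromophore; ties take the lowest channel
  index, zero-variance candidates are skipped, and if no candidate
  survives the GLM simply omits the regressor with a warning.
* The short-separation column is regressed **simultaneously**, not
  pre-subtracted, and is standardized to unit variance for conditioning
  (its coefficient is a nuisance).
* **Runs are concatenated** with run-wise drift columns, giving one HRF
  per condition per subject, matching a design in which every subject
  receives the same per-run onset vectors.
* Trial onsets are continuous in the schedule but event trains are
  discretized to the nearest sample in both the simulator and the design,
  so the basis model can represent the injected response exactly.

The solver exploits that the design is shared across channels and
subjects: the common block's normal matrix is Cholesky-factorized once,
and each channel's short-separation column enters through a rank-one Schur
complement. An explicit QR fit is the independent oracle in the tests
(agreement to 1e-8). The HRF is the basis expansion of the coefficients on
the -2..15 s lag grid, baseline-corrected by subtracting its mean over
-2..0 s (exactly zero afterwards, which also means the true pre-onset
response must be flat - the simulator's kernels are).

## Group statistics

ROI analysis averages HRFs (unweighted) over each region's surviving
channels: six regions per hemisphere (IFG/PMv, M1, IPL/SMG, MOG, TPJ,
STS). The packaged channel-to-ROI map is a plausible partition of the
schematic probe and can be replaced by a YAML file when channel-level
anatomy is available.

"Mean peak activation" is the *mean* of the HRF over a fixed window - not
the within-window maximum - with the same window for both conditions of a
contrast: 2-8 s for execution contrasts, 7-10 s for observation versus
control, 6-12 s for observation complex versus simple. Contrasts are
paired t tests on these windowed means (HbO is the inferential
chromophore; it has the better signal-to-noise ratio, and HbR is carried
descriptively). Shapiro-Francia normality checks of the paired differences
are reported *alongside* the t results, never silently switched to a
nonparametric test. Benjamini-Hochberg control at FDR 0.05 is applied
separately per hemisphere within each contrast (a family of six ROIs).
Confidence bands are pointwise - mean +/- t-quantile times the standard
error at every lag - and are not simultaneous bands; the windowed t tests,
not the pointwise bands, are the inferential surface. Time-to-peak is the
lag of the post-onset maximum for HbO and of the maximal *decrease* for
HbR, with boundary peaks flagged.

Degenerate paired tests: identical samples report t = 0, p = 1 (no
evidence) with a degeneracy flag; a constant non-zero difference leaves t
undefined and is reported as such.

## Image reconstruction

Channel-space window means $y$ map to voxel images via the sensitivity
operator $A$ and the minimum-norm Tikhonov inverse

$$X = A^{\mathsf T}(AA^{\mathsf T} + \lambda I)^{-1} y,\qquad \lambda = 0.01,$$

computed by Cholesky solve, never an explicit inverse. $\lambda$ applies to
the unscaled identity exactly as written (a `scaled` option multiplies it
by $\max \operatorname{diag}(AA^{\mathsf T})$ for users of that
convention). Windows are the -2..0 s baseline and consecutive 3 s
post-onset windows; the group-mean HRF (not per-subject images) is
inverted. The packaged sensitivity builder is deliberately *toy*: Gaussian
kernels at each channel's source-detector midpoint on a flattened 0.5 cm
grid, width half the separation, unit row sums. It provides a plausible
non-negative operator with overlapping supports for algebra-level testing;
it is not a photon-transport model, and reconstructions carry no claim of
anatomical accuracy.

## The forward simulator

The generator is first-class, tested code; its defaults *are* the study
conditions everything downstream is validated against: five conditions
(execution and observation of a simple and a complex hand action, plus a
visual control), 7 trials per condition per run, 4 s trials, ISIs drawn
from 2-17 s and rescaled (clip-and-redistribute) so that a 15 s baseline +
35 trials + ISIs fill 350 s exactly, three runs per subject sharing the
same onset vectors, 21 subjects.

Trial responses are unit-peak two-gamma kernels scaled by molar
amplitudes. Execution conditions peak at 6 s with an HbR trough delayed
3 s; observation and control conditions rise slowly to a 10 s peak with an
HbR trough that tracks HbO - the temporal signature distinguishing
executed from observed actions. HbR is -1/3 of the HbO amplitude. Kernels
taper to zero by 15 s (raised cosine over the last 3 s): responses are
modeled as completing within the deconvolution window, which is what makes
unbiased recovery well-defined; real responses with longer tails would
alias into neighboring estimates.

Amplitudes (base 0.4 uM HbO peak everywhere; injected regional effects
+0.35 uM) decompose multiplicatively per subject into a global gain
(N(1, 0.15^2)), a condition-level modulation shared across all channels
(N(1, 0.2^2)) - modeling session-wide vigilance/arousal modulation of the
neurovascular response - a regional responsiveness shared across
conditions (N(1, 0.25^2)), and a small independent residual (0.03 uM).
This structure has a statistical consequence worth stating: because the
condition modulation is global, paired condition differences in *null*
regions are positively correlated across ROIs, which is both what global
physiology does in real group data and what makes exact recovery of the
significant-ROI set a reachable target - with fully independent null
regions, the step-up procedure would admit at least one false ROI in
roughly one study in five no matter how strong the true effects are.

Nuisance structure: globally coherent sinusoidal physiology (cardiac
1.1 Hz, respiratory 0.25 Hz, Mayer waves 0.095 Hz; per-channel log-normal
gains, common phase per run), a band-limited (< 0.3 Hz) superficial series
per hemisphere seen at gain 1 by short channels and gain 0.4-1 by long
channels (this shared structure is what short-separation regression
exploits), slow per-channel drifts, spike (0.4 s FWHM Gaussian) and step
artifacts at magnitudes of 10 and 5 channel SDs with random sign affecting
a quarter of the channels, and white detector noise at 0.3% of the 100 dB
baseline intensity. The instrument's true DC level and noise spectrum are
not public; these defaults were chosen once for physiological
plausibility and testability, and are flagged as package choices, not
measured values.

What the simulator does *not* emulate: photon transport and layered
scalp/skull optics (channel sensitivity is an abstraction), serially
correlated physiological noise beyond the sinusoid-plus-band-limited
model, subject head geometry, condition-correlated motion, or behavioral
variability. Passing the package's tests therefore demonstrates that the
*analysis* is correct and calibrated under a faithful signal model - not
that any particular real dataset satisfies that model.

## Problem sizes and reproducibility

The test suite exercises single runs and small probes for unit checks, and
full 21-subject, 3-run studies for end-to-end checks; the replicate-study
calibration uses 50 studies at the full design (about 20 s per study on
one CPU, with the per-sample loops in C++ and the GLM solved at the 5 Hz
analysis rate). Every random quantity derives from a single integer seed
through fixed child-seed derivation; re-running a study with the same
configuration and seed is bit-identical, and every written result carries
the configuration's MD5 hash. Measurement noise is generated in the
forward kernel by Marsaglia polar normals driven by R's uniform generator,
so it too is fully determined by the seed.

## Known limitations

* The probe geometry is schematic (two flattened panels); only separations
  and channel counts are contractual, and the ROI map is positional, not
  anatomical.
* Wavelength count is fixed at two; the MBLL solve is the exact 2x2 case.
* No prewhitening: OLS standard errors ignore serial correlation, which is
  why inference is carried at the group level across subjects rather than
  within-subject.
* The reconstruction operator is a stand-in; localization statements are
  limited to "within one kernel width" on the toy operator.
* Real instrument dB conventions differ; the pruning thresholds assume
  intensities scaled like the simulator's.
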