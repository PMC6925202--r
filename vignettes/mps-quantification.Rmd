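---
title: "Quantifying the axonal membrane periodic scaffold: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the axonal membrane periodic scaffold: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpscope)
```

## The biological problem

Axons are lined by a membrane-associated periodic scaffold (MPS):
circumferential actin rings connected by spectrin tetramers, repeating every
~185–190 nm along the axon. The scaffold is invisible to diffraction-limited
microscopy; it is resolved by single-molecule localization microscopy (SMLM),
which yields a table of fluorophore positions rather than an image, and by
platinum-replica electron microscopy (PREM) of unroofed neurons, where the
rings appear as regularly spaced "braids" of two intertwined actin filaments
perpendicular to the axon axis. `mpscope` implements the quantitative
analysis used to characterize this scaffold in both modalities, the
registration between them, and a synthetic-scene generator so each stage can
be validated against known ground truth.

## The periodicity statistic

Let $v_1, \dots, v_N$ be an intensity profile sampled at uniform arc-length
step $\Delta$ (here $\Delta = 16$ nm, the reconstruction pixel) along a
traced axon. The normalized autocorrelation is

$$AC(k\Delta) \;=\; \frac{\sum_{i=1}^{N-k} (v_i - \bar v)(v_{i+k} - \bar v)}
                        {\sum_{i=1}^{N} (v_i - \bar v)^2},$$

the *biased* estimator: the denominator uses all $N$ terms at every lag, so
$AC(0) = 1$ and $|AC(k)| \le 1$ always. The alternative unbiased estimator
(normalizing by $N - k$) can exceed 1 at large lags and makes curves from
tracings of different lengths harder to average; since the published
protocol does not name its estimator, the biased form is this package's
declared choice. `autocorrelate()` evaluates it by FFT and is tested against
the direct $O(N^2)$ sum to $10^{-10}$ relative error.

Two quantities are derived per condition:

* **Spacing $s$** — the position of the first non-zero peak of the
  autocorrelation curve averaged over all tracings of a condition.
  `fit_spacing()` locates the highest local maximum on the lag grid inside a
  search window (default 100–300 nm) and refines it by a least-squares
  Gaussian-plus-offset fit over ±64 nm. The published protocol says only
  that the peak was "fitted" in a graphing program; Gaussian-plus-offset is
  this package's declared peak model, with a quadratic-vertex fallback, and
  the two are regression-tested to agree within ~2 nm on smooth synthetic
  curves. When two grid maxima tie, the smaller lag wins (first-peak
  semantics). A curve with no interior maximum in the window — e.g. an axon
  whose actin has been disassembled pharmacologically — raises a typed
  `no-peak` error rather than returning a number.
* **Amplitude** — $AC(192\,\mathrm{nm}) - AC(96\,\mathrm{nm})$, the value at
  the approximate first peak minus the approximate first valley
  (`ac_amplitude()`). The lags are fixed by convention, not adapted to the
  fitted peak, and are exact grid points at 16 nm sampling ($192 = 12
  \times 16$, $96 = 6 \times 16$); off-grid sampling is handled by linear
  interpolation. Amplitudes are computed per tracing and compared between
  conditions; group comparison needs the per-tracing values.

Profiles are extracted by `extract_profile()`: the polyline tracing is
resampled at the pixel pitch and, at each sample, intensity is averaged over
a band perpendicular to the local path direction (bilinear interpolation).
The band width defaults to 160 nm — the scale of an axon's apparent width in
a 2-D reconstruction — because the protocol does not state the averaging
width used; it is configurable per trace.

## Reconstruction

`reconstruct()` renders localization tables at a physical pixel size
(default 16 nm, the analysis grid). The default mode is a pure count
histogram with half-open pixel bins: counts are what the autocorrelation
operates on, conservation is exact, and boundary localizations are assigned
deterministically. A Gaussian mode (unit-integral kernel per localization,
width from `blur_sd` or each record's uncertainty) is provided for display
and for uncertainty-weighted rendering; on synthetic scenes the fitted
spacing is insensitive to the mode. Image bounds default to the tight
bounding box of the localizations (padded by $3\sigma$ in Gaussian mode), so
an emitter closer than ~3–4 σ to the auto-chosen border loses a small
fraction of its kernel mass; pass explicit `bounds` when exact conservation
near borders matters.

Coordinates are physical nanometres everywhere, origin at the top-left
pixel center, y increasing downward.

## Localization I/O

Two delimited-text dialects are supported: a tab-separated N-STORM-style
export (`Channel Name`, `Xc`, `Yc`, `Photons`, `Frame`, `Lateral
Localization Accuracy`) and the ThunderSTORM CSV convention
(`frame, x [nm], y [nm], intensity [photon], uncertainty [nm]`). Both store
coordinates in nm; translation preserves all shared fields exactly (numbers
are written at full double precision). Photon filtering
(`filter_photons()`) uses a *closed* interval — the protocol rejects "too
low and too high photon counts" without stating whether the bounds are
inclusive, so inclusivity is declared here. No photon thresholds are
built-in defaults; they are data-dependent settings.

## PREM morphometry

The braid measurement protocol averages five traced lines per data point
(`line_set()`, `distance_datapoint()`): between consecutive braids for
spacing, across a single braid before/after splitting for width. Widths of
individual filaments are operationalized as the full width at half maximum
of a cross-sectional intensity profile above local background
(`width_profile()`; background = median of the profile's end samples).
The original measurements were manual on replica images and do not define
"width" operationally; FWHM is this package's declared choice, validated on
synthetic ridges of known width: a 7 nm filament carrying ~2 nm of platinum
is modeled with apparent width $7 + 2 \times 2 = 11$ nm, the upper edge of
the 9–11 nm range reported for replicated single actin filaments. An
optional structure-tensor obliquity correction compensates cuts up to ±20°
off the ridge normal; it is off by default to mirror the manual protocol.
`summarize_morpho()` reports mean ± SEM; a single data point yields SEM 0
with a warning rather than an error so pilot analyses do not fail.

## Correlative registration

`fit_affine()` estimates the full 6-parameter planar affine map from ≥3
non-collinear control-point pairs by linear least squares (QR), matching
the transform class used to align SMLM reconstructions onto high-
magnification EM views; a similarity-constrained mode (4 parameters) is
available for low point counts. Residuals are reported as RMS in the EM
(target) frame, the frame in which biological distances are read. For $n$
points with isotropic noise $\sigma$ per coordinate, the expected 2-D
per-point residual RMS is $\sigma\sqrt{(2n-6)/n}$; the tests assert this.
`overlay_correlative()` resamples SMLM content into the EM grid:
localizations are transformed exactly and re-rendered (no double
interpolation); images are inverse-mapped with bilinear sampling.

## Statistics

`compare_groups()` follows the study's scheme: two conditions are compared
by a two-tailed Mann–Whitney U test; three or more by a Kruskal–Wallis
omnibus test with pairwise post-hoc comparisons. The published description
("non-parametric ANOVA followed by Tukey post-test") is internally
inconsistent — Tukey's HSD is a parametric procedure — so the default
post-hoc is Dunn's rank-based z test with Holm correction, the standard
companion to Kruskal–Wallis, with parametric ANOVA + Tukey HSD available
via `posthoc = "anova_tukey"`. Significance codes are ns / * / ** / *** at
0.05 / 0.01 / 0.001, and groups are summarized as mean ± SEM.

## The synthetic-scene generator

`make_mps_localizations()` emulates the statistical structure the analysis
assumes: a straight axon segment with rings at $k \cdot$`period` plus
independent Gaussian jitter (no cumulative drift — the autocorrelation model
of a fixed spacing), each ring contributing a Poisson number of labels
spread uniformly across the axon width, everything blurred isotropically by
the localization precision, plus uniform background. Defaults: period
185 nm (the spectrin tetramer spacing); jitter 5 nm; axon 4 µm (~21 rings,
the 1–2+ µm scale at which axons are locally straight); width 300 nm;
precision 10 nm and ~3000 photons/localization (typical dSTORM values);
50 labels/ring and 1 background localization/µm², chosen for testability
since no labeling-efficiency or background figures are published. Photon
counts are log-normal (a positive, right-skewed model; none is published).
`make_braid_image()` renders braids as Gaussian-cross-section ridges whose
FWHM equals the apparent filament width, two filaments per braid separated
by `braid_gap` (0 when tightly braided); `make_correlative_pair()`
expresses one ring geometry in both the SMLM and EM frames through a known
affine transform with jittered fiducial pairs. Every generator is a pure
function of its seed (bit-identical reruns, caller's RNG untouched) and
returns its ground truth alongside the scene.

What the generator does **not** emulate: blinking/photophysics kinetics and
repeated localizations of one fluorophore, drift, 3-D structure, axon
curvature, filament crossings, electron-optics image formation, and — most
importantly — any axial extent of the rings themselves (rings are axially
delta-like before blurring). Passing tests on these scenes therefore
validate the estimators' correctness and calibration, not robustness to
every artifact of real micrographs.

## A known limitation of the fixed-lag amplitude

Because the synthetic rings are axially thin, sweeping the localization
precision from 5 to 50 nm does *not* decrease the fixed-lag amplitude
monotonically, and the corresponding end-to-end test documents this by
failing: at 5 nm precision the profile is a sharp comb whose power sits
largely in higher harmonics, so $AC(192) - AC(96)$ is only ~1; moderate
blur (~30–40 nm) concentrates power into the 190 nm fundamental and
*raises* the amplitude toward its sinusoidal maximum before further blur
washes the periodicity out. The amplitude is a sinusoidality statistic at
one harmonic, not a general periodicity-strength measure; interpreting
amplitude differences between conditions as degradation is sound only when
the underlying profiles are already near-sinusoidal (as real,
optically-blurred ring labels are) rather than comb-like. The spacing
estimate is unaffected.

## Numerical choices and degenerate inputs

* Half-open pixel binning; tie lags resolved toward smaller lag; Gaussian
  peak fit initialized at the grid peak with 32 nm width.
* Zero-variance profiles raise an error from `autocorrelate()` (not NaN
  propagation); profiles shorter than 24 samples (two 192 nm lags at 16 nm)
  are rejected.
* Affine linear parts with $|\det| \le 10^{-12}$ are rejected at
  construction; collinear control points raise a rank-deficiency error.
* `width_profile()` refuses cuts with no peak above local background or
  with unresolvable half-maximum crossings.

## Problem sizes used in the test suite

The suite validates on deliberately small scenes — 4 µm axons (~21 rings),
~1000–2000 localizations per scene, 10 seeds for parameter-recovery runs,
256×512 px braid images, 20 seeds for registration recovery — sizes at
which every property under test (estimator bias, conservation, analytic
widths) is already expressed. The full suite runs in a few seconds.

## Reproducing the headline quantities

`scripts/acceptance.R --seed <int> --out <path>` regenerates synthetic
scenes at the defaults above and recomputes, from scratch: the fitted MPS
spacing and per-tracing amplitude from ten simulated tracings, the
five-line braid spacing (mean ± SEM over ten braid views with 20 nm
positional jitter, emulating the biological spread behind the published
184 ± 4 nm), the FWHM of a replicated single filament, and the mean
registration residual under 5 nm fiducial noise.
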