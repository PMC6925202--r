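# mpscope

Quantification of the axonal **membrane-associated periodic scaffold (MPS)**
— the lattice of circumferential actin rings spaced every ~185–190 nm by
spectrin tetramers that lines axons — from single-molecule localization
microscopy (SMLM) tables and platinum-replica electron microscopy (PREM)
images. The package is aimed at neuronal cell-biology and super-resolution
labs that need a scripted, testable version of the standard MPS analysis
instead of a chain of ImageJ/Prism manual steps.

## What it computes

For an intensity profile $v_i$ sampled every $\Delta = 16$ nm along a traced
axon, the normalized (biased) autocorrelation

$$AC(k\Delta) = \frac{\sum_i (v_i-\bar v)(v_{i+k}-\bar v)}{\sum_i (v_i-\bar v)^2}$$

carries the scaffold periodicity: the position of its first non-zero peak is
the **spacing** $s$ (located on the lag grid, refined by a
Gaussian-plus-offset fit), and $AC(192\,\text{nm}) - AC(96\,\text{nm})$
(first peak minus first valley) is the **periodicity amplitude**. Around
this core the package provides:

* `read_localizations()` / `write_localizations()` / `filter_photons()` —
  N-STORM text and ThunderSTORM CSV dialects, lossless translation,
  closed-interval photon filtering;
* `reconstruct()` — histogram or Gaussian super-resolution rendering at a
  physical pixel size (default 16 nm), TIFF + JSON-sidecar I/O;
* `extract_profile()`, `autocorrelate()`, `average_curves()`,
  `fit_spacing()`, `ac_amplitude()`, `measure_periodicity()` — the
  periodicity pipeline;
* `line_set()`, `distance_datapoint()`, `width_profile()`,
  `trace_length()`, `summarize_morpho()` — PREM braid morphometry: the
  five-line averaging protocol for braid spacing/width, FWHM filament
  widths, braid lengths;
* `fit_affine()`, `apply_affine()`, `overlay_correlative()` — control-point
  affine registration of SMLM data onto EM views and two-channel overlays;
* `compare_groups()` — Mann–Whitney / Kruskal–Wallis + Dunn(Holm) group
  comparison with mean ± SEM and significance codes;
* `make_mps_localizations()`, `make_braid_image()`,
  `make_correlative_pair()` — seed-deterministic synthetic scenes with
  ground truth, so every estimator is validated without microscope data.

## Worked example

Simulate a 4 µm axon with 185 nm rings, reconstruct at 16 nm/px, trace it,
and measure the scaffold:

```r
library(mpscope)

sc   <- make_mps_localizations(scene_params(period = 185, seed = 42))
locs <- filter_photons(sc$locs, min_photons = 500, max_photons = 50000)
img  <- reconstruct(locs, pixel_size = 16)

y_mid <- img$origin[2] + (nrow(img$pixels) - 1) / 2 * img$pixel_size
tr <- polyline(rbind(c(img$origin[1] + 32,                        y_mid),
                     c(img$origin[1] + (ncol(img$pixels) - 3) * 16, y_mid)),
               band_width = 300)
measure_periodicity(img, tr)
#> periodicity: spacing s = 184.4 +/- 0.2 nm (1 tracings)
#>   amplitude = 0.904 +/- NA (per-tracing mean +/- SEM)
```

The fitted spacing recovers the generating 185 nm period to within a
fraction of a pixel; the amplitude (~0.9 for this ring-comb profile) is the
per-tracing periodicity-strength statistic that group comparisons operate
on. The same scaffold seen as braids in synthetic PREM views, measured with
the five-line protocol:

```r
pts <- unlist(lapply(1:5, function(i) {
  b <- make_braid_image(braid_scene_params(spacing = 184,
                                           spacing_jitter_sd = 20,
                                           noise_sd = 10, seed = 42 + i))
  vapply(braid_spacing_datapoints(b$image), function(p) p$value, numeric(1))
}))
s <- summarize_morpho(pts)
sprintf("braid spacing: %.1f +/- %.1f nm (n = %d)", s$mean, s$sem, s$n)
#> [1] "braid spacing: 180.2 +/- 5.0 nm (n = 20)"
```

A thin command-line front end over the same functions is installed at
`inst/cli/mps-scope.R` (`simulate`, `convert`, `filter`, `render`,
`periodicity`, `morpho`, `register`).

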