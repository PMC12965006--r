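# odsmlm

Simulation and analysis toolkit for **orthogonally dispersed spectroscopic
single-molecule localization microscopy** (ODsSMLM), with reference engines
for conventional sSMLM and symmetric-dispersion sSMLM (SDsSMLM).

## The problem and who this is for

sSMLM records, for every blinking fluorophore, both its position and its
emission spectrum by dispersing the fluorescence on the camera — the basis
of multicolor super-resolution imaging with spectrally adjacent dyes
(e.g. AF647 at ~668 nm and CF660C at ~679 nm). Conventionally the photon
budget is split between a spatial (zeroth-order) and a spectral channel,
degrading both position and color precision. The orthogonal-dispersion
layout records two spectral channels dispersed along *perpendicular* axes:
every photon then serves both tasks, and combining the four raw coordinates
cancels the molecule-to-molecule spectral offset exactly, restoring
isotropic lateral precision.

This package is for microscopists and method developers who want to
simulate these channel geometries, benchmark the localization and spectral
estimators against each other, and analyze dispersed single-molecule data
in tabular (tibble) form.

## The estimator at its core

With `xh, yh` = (spectral centroid, Gaussian-fit center) of the
horizontally dispersed channel and `xv, yv` the same for the vertical
channel, the spectral offset `s` enters as `xh = x + s`, `yv = y + s` while
`xv = x`, `yh = y` stay clean. Averaging the two offset estimates
`Δλx = |xh − xv|`, `Δλy = |yv − yh|` and substituting back collapses both
sign cases to one closed form, used unconditionally:

```
x = (3·xv + xh + yh − yv) / 4        y = (3·yh + yv + xv − xh) / 4
Δλ = (Δλx + Δλy) / 2                 λc = λ_ref + Δλ·d
```

Any common spectral shift cancels exactly. The spectral centroid is also
computed from the two-channel *averaged spectrum* (the default
`lambda_c_nm`), and axial position comes from a biplane FWHM calibration of
the two channels' distinct focal planes.

## Worked example

```r
library(odsmlm)

cfg     <- optical_config()                       # 100 nm px, 6 nm/px, biplane ±250 nm
spectra <- list(AF647 = make_dye_spectrum("AF647"))

# 500 blinking events of one dye, 3000 signal photons each
events <- tibble::tibble(frame = 1:500,
                         x_nm = runif(500, 0, 100), y_nm = runif(500, 0, 100),
                         z_nm = 0, dye = "AF647",
                         n_signal = 3000, n_background = 10000)
locs <- localize_events(events, "od", cfg, spectra, seed = 1)

sd(locs$x_nm - locs$true_x_nm)   # 8.70  -> lateral precision ~8.7 nm
sd(locs$y_nm - locs$true_y_nm)   # 8.66  -> isotropic (x ≈ y)
sd(locs$lambda_c_nm)             # 0.73  -> spectral precision ~0.7 nm
```

At a 3000-photon budget and 6 nm/pixel dispersion the orthogonal geometry
localizes to ~8-9 nm *per axis* (isotropic) while simultaneously estimating
the emission centroid to better than 1 nm — there is no spatial/spectral
trade-off because no photon is spent on only one task.

Higher-level benchmarks:

```r
run_precision_sweep(cfg, "dispersion", 1:10, methods = c("od", "sd"), n_rep = 200)
run_crosstalk_sweep(cfg, dispersions = c(2, 4, 6, 8, 10), n_events_per_dye = 1000)
run_frc_benchmark(cfg, methods = c("od", "sd"))
```

A thin CLI over the same functions lives at `inst/cli/odsmlm.R`
(`simulate`, `localize`, `evaluate`, `reconstruct`, `sweeps`, `benchmark`).
The methods vignette (`vignettes/odsmlm-methods.Rmd`) documents the forward
model, the spectral-extraction design and its limitations.

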