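# radialtherm

Continuous MR thermometry for catheter ablation monitoring from **ungated
golden-angle radial** gradient-echo acquisitions: simultaneous catheter
micro-coil tracking, per-spoke rigid 2D motion correction in k-space, a
motion-state multibaseline library, and direct proton-resonance-frequency
(PRF) temperature estimation from highly undersampled radial k-space — plus
a synthetic acquisition simulator that makes the whole chain testable with
exact ground truth.

It is written for MR-physics and interventional-imaging researchers who want
a self-contained, vendor-neutral reference implementation of this processing
chain that runs on a laptop.

## The method in brief

PRF thermometry reads a temperature change from gradient-echo phase,
`theta = 2*pi*gamma*B0*alpha*1e-6*TE*deltaT` (about −0.080 rad/°C at 1.5 T,
TE 20 ms).  A continuous radial golden-angle acquisition (spokes rotated by
111.25° each TR) provides:

* **tracking** — each micro-coil spoke's 1D FFT peaks at the coil's projected
  position; two consecutive projections localise the catheter in 2D every
  2·TR = 48.28 ms;
* **motion correction** — each spoke is multiplied by the shift-theorem
  phase ramp `exp(+2i*pi*k_r*(dx*cos(rho)+dy*sin(rho))/FoV)`;
* **thermometry** — a window of 20–40 spokes (0.48–0.97 s, acceleration
  2.88–17.28) is fitted directly in k-space with the hybrid
  multibaseline/referenceless model
  `y = E[(B w) exp(i(A c + theta))] + noise`, where `B` holds motion-binned
  baseline images learned before heating, `A` a 6th-order polynomial basis
  absorbing B0 drift, and `theta` is the temperature phase, regularised by an
  l1 penalty (lambda) and a second-order roughness penalty (beta).

## Worked example

Simulate a moving phantom with a heating catheter, run the whole pipeline,
and look at the summary:

```r
library(radialtherm)
cfg <- pipelineConfig("phantom", seed = 4,
                      scene = list(n_pix = 64L, n_channels = 3L),
                      n_learning_spokes = 600L, n_stability_spokes = 200L,
                      n_heating_spokes = 300L, resolution_mm = 220 / 64,
                      binning = list(scheme = "1d", n_bins = 6L))
res <- runPipeline(cfg)
str(res$summary[c("frame_spacing_s", "acceleration", "n_bins",
                  "roi_mean_sd_degC", "peak_deltaT_degC")])
#> List of 5
#>  $ frame_spacing_s : num 0.966
#>  $ acceleration    : num 2.51
#>  $ n_bins          : int 6
#>  $ roi_mean_sd_degC: num 0.295
#>  $ peak_deltaT_degC: num 21.6
```

The frames advance by 40 spokes × 24.14 ms = 0.966 s; the undersampling
factor is the radial Nyquist count over 40 spokes; `roi_mean_sd_degC` is the
temperature uncertainty (mean over an unheated ROI of each voxel's temporal
SD after the training period), and `peak_deltaT_degC` the fitted hotspot
peak near the end of the heating ramp.

Lower-level entry points mirror the pipeline stages: `simulateAcquisition()`,
`trackCatheter()`, `correctAll()`, `prewhitenAndCompress()`,
`truncateReadout()`, `assignBins1d()`/`assignBins2d()`, `buildLibrary()`,
`kspaceFit()`, `runSeries()`, `temporalFilter()`, `roiUncertainty()`.  A thin
command-line front end lives in `inst/cli/radialtherm.R`.  The methods
vignette (`vignettes/radialtherm-methods.Rmd`) documents the models, the
numerical choices and the simulator's scope.

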