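# caclean

Detection and characterisation of individual excitation-contraction-
coupling (ECC) couplon sites — the functional units formed by L-type
Ca²⁺ channels and apposed ryanodine receptor clusters — from fast
confocal recordings of the upstroke of electrically evoked Ca²⁺
transients in cardiomyocytes.

The difficulty is that thousands of couplons fire within ~50 ms and
their local signals immediately fuse into the global transient. The
package untangles them with a diffusion-aware adaptation of the
astronomer's CLEAN deconvolution. For consecutive frames F(t₀), F(t₁)
separated by Δt,

    F(t₁) = F(t₀) ⊛ Φ_{D,Δt}  +  R,

where Φ is the discrete 2D diffusion kernel
(exp(−(x²+y²)/(4DΔt)), unit-normalised; D = 60 µm²/s for Ca²⁺-dye
complexes) and R is the newly released fluorescence that pure
diffusion cannot explain. Each release frame R is decomposed Högbom-
style: repeatedly locate the brightest pixel, and while it exceeds a
noise-calibrated threshold, subtract a tiny diffusion-shaped
"Analytical CLEAN Object" (ACO; constant K = D/2, peak a small
fraction of the frame maximum) centred there and record the centre.
The accumulated centres form the couplon map, which is watershed-
segmented into sites with centroid, area, amplitude and Gaussian FWHM
(2s convention). A rebuild step runs the process in reverse —
diffusion forecast + counts ⊛ ACO, minus a 0.00219/ms removal rate —
to verify the decomposition reproduces the recording.

Everything needed to validate the method ships with the package: a
generator for elementary release events (exponentially-modified-
Gaussian time course, growing Gaussian footprint), mixed
Poisson–Gaussian camera noise, gridded/random whole-cell simulations,
and the calibration experiments (stop-threshold calibration on
noise-only series, lateral two-event resolution, axial response,
noise tolerance, D/K constant sweeps). Couplon statistics include
density, re-fire rate, firing probability, temporal/spatial
coefficients of variation, map correlation, structure-only SSIM, FFT
periodicity and 3D stacking of per-plane maps.

## Worked example

Simulate a small cell with 12 release sites under recording-level
noise, run the full detection pipeline, and compare with the ground
truth:

```r
library(caclean)

mask <- make_cell_mask(96, 96, pixel_size = 0.215)
sim  <- simulate_random_transient(mask, n_events = 12, seed = 42)
sim$stack
#> fl_stack: 12 frame(s), 96 x 96 px, dt = 6.8 ms, px = 0.215 um
#>   intensity range [-20.2, 379] a.u.

run <- caclean_pipeline(sim$stack, mask = mask,
                        config = clean_config(threshold = 12,
                                              aco_fraction = 1e-3))
run$result
#> couplon_result: 11 release frame(s), 96 x 96 px, 468 map pixels > 0
#>   total CLEAN iterations: 41072; threshold 12, ACO fraction 0.001

head(run$sites[, c("x_um", "y_um", "amplitude", "peak", "fwhm_um")], 4)
#>        x_um      y_um amplitude      peak   fwhm_um
#> 1 19.035427  8.967361  644.6994  94.24705 1.2846864
#> 2  5.861718 13.701311  283.7852 144.50331 0.4463253
#> 3 15.100060 13.474761  386.9639  69.92517 0.9088633
#> 4  3.803353  8.781746  775.3537  81.40529 1.7423871

couplon_density_2d(run$sites, mask, 0.215)
#> [1] 40.60307
```

Nine of the twelve detections fall within 0.5 µm of a true release
site; the table columns are the site centroid (µm), integrated map
amplitude and peak (a.u.), and the fitted FWHM (2s, µm). The density
is sites per 1000 µm² of cell mask. The detection threshold of 12 is
the value the package's own calibration yields for its default
denoiser (see `calibrate_threshold()` and the methods vignette).

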