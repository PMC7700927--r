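# gammaQC

Automated, quantitative quality control for gamma cameras and SPECT
systems, built for the two phantoms a clinical nuclear-medicine QC
programme actually runs: the four-quadrant bar phantom (planar spatial
resolution) and the ACR/Jaszczak-style SPECT phantom (cold-sphere contrast
detectability, cold-rod resolution, tomographic uniformity). Routine visual
reads of these phantoms are imprecise and reader-dependent; `gammaQC`
replaces them with deterministic ROI statistics, threshold interpolation
and longitudinal control charts, while keeping the worksheet workflow a
technologist already knows.

## What it computes

**Bar phantom — SD-based MTF.** The phantom is detected by morphological
closing, Gaussian smoothing and relative thresholding; a 132 mm circular
ROI is placed in each quadrant at fixed offsets from the detected centre
(±134, ±104 mm for the rectangular phantoms; ±106, ±106 mm for the square
one). For a quadrant with bar width *w* (one line pair = 2*w*, frequency
*f* = 1/2*w*), the modulation transfer is estimated from the ROI's pixel
statistics:

```
MTF(f) = (π√2 / 4) · sqrt(max(SD² − mean, 0)) / mean
```

where the subtracted mean removes the Poisson counting variance so that a
structure-free flood reads ≈ 0. Linear interpolation of bar width against
MTF reports the bar width at MTF 0.15 and 0.10 (largest three bars;
thresholds 0.5/0.25 over the largest four bars for the coarse square
phantom). Per-device histories yield μ ± 3σ control limits per bar size.

**ACR phantom.** Per reconstructed transaxial slice, after the same
detection step:

* spheres — `CNR = (B̄ − S̄) / SD_B` between each cold-sphere ROI and a
  69.2 mm central background ROI, and the lesion size at CNR = 3 (the lower
  Rose-criterion limit) interpolated across the three smallest spheres;
* rods — a 72 mm line ROI across the outer rod row of each sector, sampled
  at quarter-pixel steps; the near-sinusoidal profile's modulation is
  `√2 · SD(detrended) / mean`, averaged over ten slices, with the rod size
  at modulations 0.1–0.5 interpolated across the five largest sectors;
* uniformity — the CT-style five-ROI test: percent deviation
  `100 · (P̄ᵢ − C̄) / C̄` of four peripheral 50 mm ROIs from the central one.

A worksheet evaluator applies the pass/fail rules (visual bar entry
\> 3.0 mm fails; MTF outside μ ± 3σ fails; interpolated width at MTF 0.12
above 3.0 mm fails) and an append-only CSV history maintains the control
charts.

**Synthetic phantoms.** Every stage is testable without clinical data: the
simulator renders bar phantoms analytically (exact error-function profiles
of a Gaussian PSF, no rasterisation error) and ACR volumes with true 3-D
partial volume for the spheres, Poisson/Gaussian noise, optional
centre-depression and ring artifacts — all bit-reproducible from a seed,
with analytic ground truth attached. A minimal DICOM codec round-trips
images so the whole pipeline can be exercised from files.

## Worked example

```r
library(gammaQC)

# weekly bar-phantom QC: 5e6-count acquisition, 256 matrix
img <- simulate_bar_planar(sim_bar_config("bar1", matrix_size = 256,
                                          psf_fwhm_mm = 4.7, seed = 42))
analyze_bar_image(img, bar_template("bar1"))
#> <mtf_result> template bar1
#>  quadrant bar_width_mm        mtf
#>        Q1          3.5 0.20176794
#>        Q2          3.0 0.11220551
#>        Q3          2.5 0.04424391
#>        Q4          2.0 0.01770333
#>   bar width at MTF 0.15: 3.21 mm
#>   bar width at MTF 0.10: 2.91 mm
```

The 3.5 mm bars sit at MTF ≈ 0.20 — a camera in good order; the 2.5 and
2.0 mm quadrants are below the method's 0.1 validity floor and are
annotated as such. The interpolated width at MTF 0.15 (3.21 mm) is the
quantity to trend: it moves continuously as resolution degrades, unlike a
visual read quantised to the four bar sizes.

```r
vol <- simulate_acr_volume(sim_acr_config(seed = 11))
gt  <- attr(vol, "ground_truth")
analyze_spheres(vol, acr_template(), gt$sphere_center_slice)
#> <sphere_result> slice 18
#>  diameter_mm      cnr
#>         31.8 9.931792
#>         25.4 8.427974
#>         19.1 6.377438
#>         15.9 5.273203
#>         12.7 3.177782
#>          9.5 1.932791
#>   lesion size at CNR 3: 12.24 mm
```

CNR rises with sphere diameter as partial volume relaxes; the 12.7 mm
sphere sits in the 2.5–4 band where human observers disagree, and the
interpolated 12.2 mm lesion size at CNR 3 summarises detectability in one
number. `analyze_rods()` (ten-slice aggregate), `analyze_uniformity()`,
`slice_sweep()`, `tidy()`/`glance()`/`autoplot()` methods and
`evaluate_worksheet()` complete the workflow; `inst/cli/gammaqc.R` exposes
it all as a command-line tool.

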