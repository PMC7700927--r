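---
title: "Methods: automated bar-phantom and ACR SPECT phantom analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated bar-phantom and ACR SPECT phantom analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gammaQC)
```

## The problem

Routine gamma-camera QC rests on two phantoms. The four-quadrant bar
phantom — alternating lead bars and gaps of equal width, four widths per
phantom — probes planar spatial resolution; the ACR/Jaszczak SPECT phantom
— a Tc-99m-filled cylinder with cold-sphere, cold-rod and uniform sections
— probes tomographic contrast detectability, resolution and uniformity.
Both are traditionally read visually, which quantises the answer to the
discrete object sizes in the phantom and inherits the reader's bias.
`gammaQC` replaces the read with template-driven ROI statistics and turns
each test into a continuous, trendable number.

## Detection and ROI placement

Each image (or slice) is preprocessed with a grayscale morphological
closing (dilation then erosion, square structuring element, default 3 px)
that fills the narrow dark bars, followed for planar bar images by a
Gaussian blur (default sigma 1 px); ACR slices use the closing only. The
phantom mask is the largest connected component above a *relative*
threshold — a configurable fraction (default 0.10) of the 99.5th-percentile
intensity of the preprocessed image. The percentile anchor makes the
threshold robust to isolated hot pixels, and the relative form makes
detection invariant to global count scaling. The centre is the centroid of
the *binary* mask, not of intensity: bar quadrants have different mean
counts, and an intensity centroid would drift toward the coarse-bar
quadrants. Where several components tie in area the one with the smaller
centroid row index is chosen, so detection is deterministic.

Whether the centroid should be taken on the raw or the preprocessed image
is genuinely open; we threshold the preprocessed image, matching the order
of the processing steps, and expose the choice through the detection
parameters.

ROIs are then pure functions of (centre, template): four 132 mm circular
ROIs at (±134, ±104) mm for the rectangular bar phantoms and (±106, ±106)
mm for the square one; for the ACR phantom a 69.2 mm background ROI at the
centre plus six sphere ROIs on the sphere ring (smallest sphere at
12 o'clock, 60° spacing), six 72 mm line ROIs across the outer rod rows,
and five 50 mm uniformity ROIs (centre + 0/90/180/270°). Pixel membership
in a circular ROI is by pixel centre, with no partial-area weighting —
deterministic, fast, and at these ROI sizes (≥ 25 px² per smallest sphere
ROI is enforced) the pixelation error in the statistics is negligible
relative to counting noise.

ROI offsets are interpreted in a continuous mm frame with the origin at
the image centre, x along columns, y upward, pixel-centre convention.
Templates assume the coached phantom orientation (largest bars top-right,
smallest sphere at 12 o'clock); rotation estimation is deliberately out of
scope, as the fixed-offset design is what keeps the analysis fast and
deterministic.

### Geometry the templates cannot know

The sphere and rod physical sizes, the sphere ring radius (default 54 mm),
the outer rod-row radius (default 74 mm) and the phantom interior radius
(default 108 mm) are properties of the phantom unit, not of the method.
The defaults describe the standard commercial phantom and live in an
editable geometry file (`inst/extdata/geometry.yaml`); they must be
confirmed against the phantom's datasheet. Likewise the DICOM tags used to
assign images to devices are site policy and are configured, not
hard-coded.

## The SD-based MTF estimate

For a quadrant of bar width $w$ (frequency $f = 1/2w$) with ROI mean $\mu$
and population SD $s$:

$$\widehat{MTF}(f) \;=\; \frac{\pi\sqrt2}{4}\,
  \frac{\sqrt{\max(s^2-\mu,\,0)}}{\mu}.$$

The rationale: a blurred bar pattern is dominated by its fundamental
sinusoid, whose amplitude-to-mean ratio is the modulation; for a sinusoid
$SD = A/\sqrt2$, and the $\pi\sqrt2/4$ factor converts the square-wave
response to the sinusoidal MTF (Coltman's correction at the fundamental).
Counting statistics add variance equal to the mean, so subtracting $\mu$
from $s^2$ makes a structure-free flood read approximately zero; the
subtraction is a flag (`poisson_correct`) because it is wrong for
noise-free synthetic input and for reconstructed slices, whose noise is
not Poisson at the pixel level. A negative variance excess — common by
chance at low counts on fine bars — is clamped to zero and flagged rather
than propagated as NaN.

Two validity conditions are enforced as warnings/annotations rather than
errors: the ROI should span at least seven line-pair periods (all standard
templates satisfy this: 132 mm spans ≥ 10 periods even at 6.4 mm bars),
and estimates below 0.1 are annotated "below validity limit" and excluded
from control-limit histories by default — at that level the estimator is
noise-floor-limited, as the unblurred ceiling argument below makes
concrete.

On an exactly binary pattern the estimator reads $\pi\sqrt2/4 \approx
1.1107$ (or $\approx 1.105$ with the Poisson term subtracted at a mean of
100 counts), not 1.0 — the square-wave harmonics inflate the SD. This
ceiling is reproduced by the test suite on pixel-commensurate unblurred
simulations.

### Interpolated thresholds

Bar width is reported at MTF 0.15 and 0.10 (largest three bars) for the
fine phantoms, and at 0.5 and 0.25 (largest four bars) for the coarse
square phantom. The interpolation scans adjacent (size, value) pairs from
the largest size and linearly inverts the first bracketing segment; a
target outside the observed range returns `NA` rather than extrapolating.
The same routine serves the sphere (lesion size at CNR 3, three smallest
spheres) and rod (rod size at modulations 0.1–0.5, five largest sectors)
reports, and is shared code with shared tests.

## ACR metrics

**CNR.** $(\bar B - \bar S)/SD_B$ with the background SD as the noise
term. The denominator is not uniquely fixed by the standard contrast
definitions this adapts; a pooled-SD alternative is selectable, and the
default is declared, not asserted as identical to any prior
implementation. The sign is preserved so a hot artifact reads negative.
The Rose-criterion default threshold of 3 is configurable; the 2.5–4 band
where human observers disagree is stored as annotation only.

**Rod modulation.** The line ROI crosses the outer rod row perpendicular
to the sector bisector, so the profile is near-sinusoidal with period
twice the rod diameter. The default estimator is $\sqrt2\,SD/\mu$ after
linear detrending (robust to sampling phase and to the residual radial
intensity gradient along the chord); a peak–valley estimator over detected
extrema is available because "pixel-based modulation" admits both
readings. Values are clamped to $[0, \sqrt2]$, the binary-profile ceiling.
Profiles are sampled by bilinear interpolation at quarter-pixel steps.
Single-slice modulation is noisy — each rod's alignment with the coarse
reconstruction grid varies slice to slice — so the reporting mode averages
the per-sector modulation across exactly ten slices (analyze-then-average;
a sum-then-analyze mode over the same slices is the documented
alternative). The ten-slice requirement is enforced with an explicit
override flag.

**Uniformity.** The CT-style five-ROI percent deviation. Single-slice
uniformity is reported with an advisory flag recommending visual review:
it is a useful attenuation-correction sanity check but not a reliable
artifact detector, and the output says so rather than auto-passing.

## Control charts and worksheet rules

Per (device, metric, object size) histories are an append-only CSV;
$\mu \pm 3\sigma$ limits are computed on demand once at least 10 entries
exist (configurable). Worksheet evaluation is a pure function with two
labelled rule families: the visual rule (entered resolvable bar width
strictly greater than 3.0 mm fails — 3.0 mm itself passes), and automated
rules (any per-bar MTF outside its limits; interpolated width at MTF 0.12
above 3.0 mm). Automated failures are reported as failures but labelled
separately from the visual rule, since only the latter has an
accreditation-backed action level.

## The synthetic phantoms

The simulator validates estimators, not reconstruction physics: it renders
images in the image domain as linear blur + noise, with no
projection/FBP chain.

**Bar phantoms.** Each quadrant is a separable product of a 1-D square
wave and a 1-D window, so its Gaussian-blurred image is an outer product
of error-function profiles evaluated exactly at the pixel centres. There
is no rasterisation step and hence no aliasing error at any matrix size —
a property the matrix-size-invariance tests rely on. (An earlier
rasterise-blur-decimate implementation biased the smallest-bar response by
+0.02 through pre-blur aliasing and kernel truncation; the analytic
renderer removed both terms.) Defaults follow routine practice: 5×10⁶
total counts, a 614.4 mm field so 256/512 matrices give 2.4/1.2 mm pixels,
Poisson noise, PSF FWHM per scenario (4.7 mm puts the 3.5 mm bars at the
MTF ≈ 0.2 operating point used throughout the tests). With zero blur the
pattern is sampled directly, so unblurred images are exactly binary.

**ACR volumes.** Contiguous uniformity (12 slices), sphere (12) and rod
(14) sections at 128², 4.8/1.45 ≈ 3.31 mm pixels, 3.3 mm slices. Slices
are rasterised at 5× subsampling, blurred with an exact FFT-domain
Gaussian transfer function of the reconstruction FWHM (default 12 mm, a
representative LEHR FBP tomographic resolution), and decimated at the
pixel centres. Spheres get genuine 3-D partial volume: the cold fraction
at each pixel is the slice-thickness integral of the sphere indicator
convolved with an axial Gaussian of the same FWHM — without it, fully cold
spheres read CNR 7–13 at the smallest size, far above anything a real
reconstruction produces. Rod sectors are hexagonal lattices with centre
spacing twice the rod diameter and one lattice row exactly on the outer
rod-row radius, so the template's chord crosses rod centres. Mean
background counts default to 250 per pixel, the scale of a ~32-million
count acquisition spread over the reconstructed cylinder. Optional
artifacts: a multiplicative Gaussian-profile ring, and a centre-depression
bowl that is flat inside r = 30 mm and recovers to zero by r = 45 mm — the
taper is placed entirely between the central ROI (r ≤ 25 mm) and the
peripheral ROIs (r ≥ 45.5 mm at the default layout) precisely so the
expected uniformity deviation has the closed form $100\,c/(1-c)$ for
depression fraction $c$.

What the simulator does *not* emulate, and what passing tests therefore do
not show: streak and directional FBP noise correlations (noise is
independent per pixel, applied after blur), scatter and septal
penetration, attenuation-correction residuals beyond the radial bowl,
phantom rotation and tilt, dead pixels and linearity distortions. Results
on real acquisitions depend on those; the tests establish correctness of
the estimators and geometry, not camera-specific absolute values.

## Numerical choices

* Population SD (divide by *n*) everywhere, matching the estimator
  definitions; sample SD is used only for control-limit sigma.
* Degenerate inputs are errors with named reasons: zero background SD
  (CNR), non-positive means (MTF, modulation, uniformity), ROIs off the
  image, empty images, kernels larger than the image.
* Flat-bracket ties in interpolation return the larger size (exact knot).
* The DICOM codec stores counts as 16-bit integers (slope 1) when they are
  integral, and slope-encoded otherwise; reading applies slope/intercept
  and keeps floats thereafter. Missing pixel spacing is an error — the
  reader never assumes a default geometry.
* Bit-reproducibility: each simulation seeds the RNG locally and restores
  it; UID generation deliberately avoids the RNG.

Test and acceptance problem sizes were chosen once as the package's
standard verification scale: 100 randomised small images for the
formula-oracle suite; 25 matched seed pairs at 256² vs 512² for
matrix-size invariance; 20 noisy acquisitions for the 3.5/3.0 mm
separation check; 3 noise realizations for the sphere slice-sweep trend
and 6 for the aggregate-variance comparison. The two smallest rod sectors
(6.4, 4.8 mm) are genuinely unresolved at the default 12 mm
reconstruction FWHM — their true modulation (≈ 0.04 and 0.004) sits below
the ≈ 0.06 noise floor of the SD estimator — so strict ordering with noise
is asserted over the resolvable sectors and over all sectors only on
noise-free volumes; this mirrors what the plateau in real rod data looks
like.

## Known limitations

* No rotation handling: a rotated phantom silently degrades every metric;
  orientation must be coached, as the fixed-offset templates require.
* x/y-resolved resolution is not reported — each quadrant tests one
  detector region at one orientation.
* Interior rod rows are not analysed; only the outer row contributes.
* The uniformity test is not artifact-specific; ring/bullseye detection
  needs dedicated methods, and the output's advisory flag says so.
* The DICOM codec is deliberately minimal (uncompressed little-endian,
  no sequences); clinical archives with exotic transfer syntaxes need
  conversion first.
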