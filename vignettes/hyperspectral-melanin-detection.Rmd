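---
title: "Detecting Mie-regime melanin granules with hyperspectral OCT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting Mie-regime melanin granules with hyperspectral OCT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsoct)
```

## The physical picture

Spectral-domain OCT records, for every lateral beam position, an
interference spectrum between a reference reflection and the light
backscattered by the sample. Conventional processing Fourier-transforms
the whole spectrum and discards the wavelength dimension. Melanin
granules in the retinal pigment epithelium (RPE), however, have diameters
of roughly 0.3–1 µm — comparable to visible wavelengths — so their
backscattering coefficient $\mu_b(\lambda)$ oscillates with wavelength
(the Mie regime). A white-light OCT system that covers 440–700 nm
therefore carries a per-scatterer spectral fingerprint inside each
interferogram, and reconstructing the data in narrow sub-bands makes that
fingerprint visible as band-to-band intensity modulation. Flat-spectrum
scatterers (specular interfaces, large or sub-wavelength tissue
structures) show no such modulation, which is the contrast the
deviation-from-mean (DFM) statistic exploits.

## Optical property models

Four materials are built in (`material_index()`), all as functions of
vacuum wavelength in nm:

* **Eumelanin**: real index from an empirical inverse-even-power
  dispersion fit (1.784 at 400 nm falling to 1.694 at 700 nm) and an
  extinction coefficient $\kappa(\lambda)$ from a quartic fit to rodent
  RPE melanin absorption via $\kappa = \mu_a \lambda / 4\pi$. The quartic
  is clamped at zero against fit undershoot. Both fits are only trusted
  on 400–700 nm; evaluation outside raises an error rather than a
  warning, because polynomial fits diverge silently outside their domain.
* **Silicone elastomer** (the phantom host): a quadratic fit,
  transparent ($\kappa = 0$).
* **RPE medium**: constant 1.368, non-absorbing — the melanin dominates
  the layer's absorption.
* **N-BK7** (ball-lens glass): the standard three-term Sellmeier
  equation.

The fits take vacuum wavelength; the sources they descend from report
vacuum wavelengths, and this choice is fixed rather than configurable so
it cannot drift silently.

## Mie backscattering

`backscattering_efficiency()` implements the Mie series for an absorbing
sphere in a non-absorbing medium: logarithmic derivatives of the
Riccati–Bessel functions by downward recurrence (numerically stable for
complex argument), upward recurrence for the real-argument functions, and
the radar backscattering efficiency
$Q_b = x^{-2}\,|\sum_n (2n+1)(-1)^n(a_n - b_n)|^2$.
The series is truncated at the Wiscombe order
$\lceil x + 4x^{1/3} + 2\rceil$. Exact backscatter (not an NA-integrated
cross-section) is used because OCT detects the direct backscattered
field; plane-wave illumination is assumed, which for a weakly focused
beam only shifts the spectra slightly without changing the modulation
frequencies. The test suite checks the implementation against an
independently coded brute-force series (power-series Bessel functions,
direct coefficient ratios) to 1e-6 relative error, against the Rayleigh
closed form at small size parameter, and for energy conservation
($Q_{ext} = Q_{sca}$ for real index) at 1e-8.

`mu_b_spectrum()` converts a monodisperse granule population to
$\mu_b(\lambda) = N\, Q_b\, \pi (d/2)^2$ in mm⁻¹ under the
independent-scatterer assumption; dependent-scattering corrections at
high concentration are out of scope. `concentration_to_number_density()`
converts mg/mL to granules/µm³ using a melanosome mass density of
1.7 g/cm³ (a literature value, exposed as an argument since mass density
of synthetic eumelanin particles varies).

## Ball-lens phantom optics

The rodent-eye phantom focuses light with an N-BK7 ball lens. Instead of
ray tracing, the package uses the paraxial thick-lens focal length
$f(\lambda) = n(\lambda) D / (4(n(\lambda) - 1))$, which captures the
chromatic focal shift to within the ~15% that separates paraxial from
ray-traced best focus (spherical aberration shifts the latter slightly).
With a 500 nm reference the model gives ±25.6 µm across 400–700 nm for
the 3 mm lens and exactly double for the 6 mm lens. The confocal
parameter is $b = 2\pi w_0^2/\lambda$ with the waist taken as the Airy
radius (the phantom spot is diffraction limited); the input beam diameter
is a free instrument parameter that the source instrument never
documented, so the in-focus overlap interval (`focus_overlap_interval()`)
is reported for whatever beam model the user supplies and is not treated
as a validated number.

## The synthetic interferogram generator

`simulate_bscan()` implements the standard SD-OCT forward model

$$I(px) = S(\lambda)\Big[R_r + \sum_j r_j(\lambda) +
  2\sum_j \sqrt{R_r\, r_j(\lambda)}\,
  \cos\big(2 k n_g z_j + a_2 (k - k_0)^2 + a_3 (k - k_0)^3\big)\Big]
  + \varepsilon$$

evaluated at each detector pixel's wavelength. Design choices, and what
they emulate:

* **Source** (`source_model()`): two broad Gaussians plus a pedestal,
  with a configurable mid-band suppression dip emulating a magenta filter
  that boosts the band edges. The true filter curve is unpublished; the
  dip depth (default 0.65) is a free parameter.
* **Spectrometer** (`spectrometer_model()`): 2048 pixels uniform in
  wavelength — hence nonlinear in wavenumber, as in a grating
  spectrometer — spanning 425–730 nm. The span extends slightly beyond
  the 440–700 nm band set so the edge sub-band windows are not truncated
  at the grid boundary, which would break the uniform-resolution design.
  An optional Gaussian envelope models sensitivity roll-off.
* **Speckle** arises naturally from randomly placed sub-resolution
  scatterers interfering within the point-spread function, rather than
  from a multiplicative speckle model; this preserves the
  wavelength-dependent speckle decorrelation that motivates watershed
  binning.
* **Lateral PSF**: Gaussian amplitude spread across adjacent A-scans,
  FWHM 2.5 µm at 550 nm scaling linearly with wavelength (the system's
  estimated 2–3 µm lateral resolution).
* **Noise**: additive Gaussian detector read noise, optional shot term.
  The SNR knob is calibrated in the image domain: the requested dB value
  is the ratio of the brightest scatterer's reconstructed peak magnitude
  to the Rayleigh scale of the reconstructed noise, propagated back
  through the reference normalization and FFT gain to a detector-count
  SD. The default 45 dB puts granules — about 13 dB below the saturating
  phantom interface — near 30 dB, the regime in which the detection
  claims operate; the reference instrument reaches its SNR by averaging
  30 repeated B-scans, which the generator reproduces via `repeats`.
  Matched scene pairs (pigmented/albino) should share one calibrated
  `read_sd` rather than calibrating per scene.
* **Scenes**: `make_phantom_scene()` draws granule positions as a
  homogeneous Poisson process in a slab (default 70 µm deep, staying
  inside the unambiguous depth of the nonuniform-k sampling, with an
  out-of-plane thickness of 7.5 µm ≈ three lateral resolutions standing
  in for the volume the beam actually interrogates), log-normal diameters
  with mode 2.4 µm (the synthesized particles' measured peak), and a
  flat-spectrum interface line. `make_retina_scene()` builds weak
  flat-spectrum tissue layers plus, when pigmented, sparse RPE granules
  (0.3–1.0 µm, ~1.5 per A-scan, the Brown Norway rat regime) with the
  RPE nearest zero delay (enhanced-depth convention). The albino variant
  reuses the identical tissue realization. Granule reflectivity defaults
  render granules roughly 8× dimmer than the interface, matching the
  qualitative appearance of phantom B-scans where the interface
  saturates.

Everything stochastic is seed-controlled and bit-reproducible.

## Hyperspectral reconstruction

`reconstruct_stack()` chains the processing stages, each also exported on
its own:

1. **Background removal** — subtract the reference spectrum and divide by
   it, cancelling the source envelope; pixels with under 5% of the peak
   reference power are masked (no usable light).
2. **k-linearization** — natural cubic spline onto a uniform wavenumber
   grid. Fringes should stay below ~8 samples/cycle for faithful
   interpolation, which bounds usable depth at a given pixel count; the
   PSF-critical analyses therefore run at the full 2048 pixels.
3. **Sub-bands** — 27 Gaussian windows, centres 440–700 nm in 10 nm
   steps, one shared wavenumber FWHM $4\ln 2/(n_{tissue}\,\delta z)$ =
   0.3349 rad/µm for the 6 µm in-tissue resolution target at
   $n_{tissue} = 1.38$. Windows are peak-normalized (not area): band
   intensities then report spectral density, and since the DFM subtracts
   per-basin means this choice only sets an overall scale.
4. **Dispersion** — second/third-order phase is removed per band about
   each band centre, with the global cubic re-expanded as
   $a_2^{eff}(k_c) = a_2 + 3a_3(k_c - k_0)$; the per-band linear
   remainder is exactly the first-order dispersion that registration
   later absorbs. When the coefficients are unknown,
   `estimate_dispersion()` fits them by minimizing the Shannon entropy of
   the normalized A-scan intensities of the brightest columns — the
   sharpness metric is this package's choice, since the reference method
   is unpublished. Numerics that matter: the conjugate fringe branch is
   suppressed (analytic signal) before the search, because the trial
   phase drives it doubly-dispersed and biases the landscape; and the
   search runs coarse grid → zoomed grid → Nelder–Mead, because sidelobe
   ripple in the sharpness landscape traps a bare simplex in local
   minima about 25% from the truth.
5. **FFT and registration** — positive delays kept; band images store
   the squared magnitude, the linear intensity scale on which all
   statistics run (and the quantity proportional to scatterer
   reflectivity $r(\lambda)$ — field amplitude goes as $\sqrt r$).
   Bands are aligned by integer axial shifts maximizing cross-correlation
   of mean A-scan envelopes against the middle (570 nm) band; the
   reference instrument did this manually, automation is preferred here
   for reproducibility, and sub-pixel registration is deliberately
   deferred. Correlation ties break toward zero shift with a warning.

## The DFM statistic

`dfm_analyze()` runs the image-analysis pipeline on a reconstructed
stack: maximum-intensity projection across bands (suppressing
wavelength-dependent speckle and revealing granules visible in any band);
strict watershed on the MIP with every local maximum a seed; merging of
basins below 8 µm² (just under the resolution area) into the neighbour
sharing the longest boundary — merging rather than seed suppression, so
the area floor is enforced exactly; per-basin mean spectra over the 27
bands; mean subtraction; and
$DFM = \int_{440}^{700} |I_{dev}(\lambda)|\, d\lambda$ by the
trapezoidal rule (the integration rule is a package choice). DFM is
computed on basin-mean spectra, never per pixel: single-pixel spectra are
speckle-corrupted, which is the entire reason for the watershed binning.
A watershed tolerance above zero is available but defaults off — any
tolerance tied to the global dynamic range collapses speckle basins
whenever a bright interface dominates the image.

Thresholding and the concentration metric: the noise level is measured in
the region anterior to the detected surface (first 50%-of-column-max
crossing, median-filtered; the margin above the surface is two axial
resolutions so PSF tails stay out of the statistics). The binary map is
`map > noise_mean + k * SD` with `k = 3`. The baseline term matters:
basin-binned values of a non-negative statistic have a strictly positive
noise floor whose mean exceeds its spread, so a threshold of `k * SD`
alone would sit *below* the noise cluster and saturate the zero-signal
cases; thresholding `k` standard deviations above the floor restores the
intended meaning of "3 sigma above noise". `fraction_above_threshold()`
reports the percentage of super-threshold pixels over a 50 µm depth
window starting one axial resolution (6 µm) below the surface line, for
the intensity image and the DFM map separately, each against its own
map's noise statistics.

On synthetic phantoms this reproduces the expected concentration
behaviour: the intensity-based fraction rises monotonically across
0–30 mg/mL, while the DFM-based fraction rises to about 10 mg/mL and then
plateaus — at high density multiple granules of different diameters share
resolution cells and their modulations partially cancel, so the DFM
specifically flags *resolvable* Mie scatterers.

## What the generator does and does not emulate

The simulator reproduces the features the pipeline depends on: Mie
spectral modulation per granule, wavelength-dependent speckle from
interfering point scatterers, nonuniform wavenumber sampling, source
shaping, injected dispersion, seed-controlled noise, repeated B-scans.
It does **not** model sample motion, polarization, multiple scattering,
depth-dependent roll-off beyond an optional envelope, non-spherical
granule shapes (real RPE melanosomes are ellipsoids), granule-to-granule
melanin content variation, or ocular media absorption. Passing tests
therefore demonstrate the *method's* internal consistency — that the
pipeline recovers known spectral fingerprints under controlled conditions
— not its performance on in vivo data, where motion and shape dispersion
degrade the modulation contrast.

## Problem sizes and runtime choices

Simulated B-scans in the tests use 96 A-scans at 2 µm pitch and 1024 or
2048 detector pixels; the concentration experiment uses six
concentrations × five seeds, single B-scans each; spectral-recovery and
discrimination experiments use 2048 pixels. These sizes give stable
statistics for every property checked while keeping a full suite run in
minutes on one core. The real instrument's 512 × 400 × 30-repeat volumes
are reachable through the same API by raising the scene and simulator
parameters.

## Known limitations

* Paraxial lens model only; the ~15% gap to ray-traced focal shifts is
  inherent and documented, not correctable within scope.
* Integer-pixel band registration; sub-pixel residuals up to half a
  pixel (~0.25 µm optical) remain.
* The absolute µ_b scale of the Mie panels has no published numeric
  anchor, so validation of the spectra is structural (oscillation,
  extrema, oracle equivalence) rather than absolute.
* Basin merging is greedy per round; pathological label geometries could
  merge through a weaker neighbour, though round-based recomputation
  bounds the effect.
* The DFM is sensitive to band-dependent noise floors inherited from
  source shaping; the baseline-referenced threshold compensates at the
  statistic level rather than flattening the floors spectrally.
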