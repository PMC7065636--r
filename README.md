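# hsoct

Hyperspectral visible-light OCT simulation and melanin detection in R.

## The problem

Melanin in the retinal pigment epithelium (RPE) protects photoreceptors,
and its loss is implicated in retinal disease — but at the *low*
concentrations found in animals like the Brown Norway rat, absorption- and
polarization-based imaging contrasts fail. What remains is scattering:
RPE melanin granules are 0.3–1 µm spheres-to-ellipsoids, comparable to
visible wavelengths, so their backscattering coefficient
$\mu_b(\lambda)$ oscillates with wavelength (Mie regime), while
interfaces and bulk tissue backscatter flatly. A white-light
spectral-domain OCT system covering 440–700 nm records that fingerprint
in every interferogram; reconstructing each B-scan into 27 spectral
sub-bands and measuring per-speckle spectral modulation localizes the
granules in depth.

`hsoct` implements that method end to end for researchers in retinal
imaging and OCT signal processing:

* **Optical property models** — wavelength-dependent complex refractive
  index of eumelanin ($n(\lambda) + i\kappa(\lambda)$ from published
  dispersion/absorption fits), silicone elastomer, RPE medium, N-BK7.
* **Mie backscattering** — the series for absorbing spheres, giving
  $Q_b = x^{-2}|\sum_n (2n+1)(-1)^n(a_n - b_n)|^2$ and population
  spectra $\mu_b(\lambda) = N\,Q_b\,\pi(d/2)^2$.
* **Ball-lens phantom optics** — paraxial chromatic focal shift
  $f(\lambda) = nD/(4(n-1))$ and confocal parameter
  $b = 2\pi w_0^2/\lambda$ for the rodent-eye phantom.
* **Synthetic interferograms** — a seeded SD-OCT forward model
  (white-light source with mid-band suppression, nonlinear-in-k
  spectrometer sampling, second/third-order dispersion, Poisson granule
  scenes, flat interfaces, calibrated noise, repeated B-scans).
* **Hyperspectral reconstruction** — background removal,
  k-linearization, 27 Gaussian windows with a shared wavenumber FWHM
  $4\ln2/(n_{tissue}\,\delta z)$ for a constant 6 µm in-tissue
  resolution, numerical dispersion compensation/estimation, axial
  registration.
* **The DFM statistic** — watershed speckle binning (8 µm² floor),
  per-basin band spectra, deviation from the across-band mean,
  $DFM = \int_{440}^{700}|I_{dev}(\lambda)|\,d\lambda$, 3σ-above-noise
  thresholding, and the depth-windowed fraction-above-threshold
  concentration metric.

## Worked example

Simulate a 10 mg/mL melanin-in-silicone phantom B-scan, reconstruct the
27-band stack, and run the DFM analysis:

```r
library(hsoct)

# Mie backscattering spectrum of a 0.7 um granule in RPE medium
sp <- mu_b_spectrum(granule_population(0.7, 1e-3), material_index("rpe_medium"))
sp
#> <mie_spectrum> d = 0.7 um in rpe_medium, N = 0.001 um^-3
#>   261 wavelengths 440-700 nm, mu_b range 0.0116-0.073 mm^-1
plot(sp)   # oscillatory: the signature the DFM detects

scene <- make_phantom_scene(10, seed = 1)     # Poisson granules + interface
raw   <- simulate_bscan(scene, spectrometer = spectrometer_model(2048),
                        noise = list(snr_db = 45), seed = 1)
stack <- reconstruct_stack(raw, band_config(), dispersion = NULL)
stack
#> <hyperstack> 27 bands (440-700 nm) x 1024 depth x 96 lateral
#>   pixel pitch 0.359 um axial (in medium) x 2 um lateral
#>   registration shifts: [0, 0] px; dispersion a2=0 a3=0

an <- dfm_analyze(stack)
an
#> <dfm_analysis> 1961 basins, noise SD (DFM) 11.2, 3-sigma threshold 59.2
#>   fraction above threshold: intensity 15.30%, DFM 45.32%
```

Reading the numbers: the MIP across bands was segmented into 1961
speckle-scale basins; the DFM noise floor anterior to the lens surface
has SD 11.2 (intensity·nm), putting the 3σ threshold at 59.2; within the
50 µm analysis window below the surface, 15.3% of pixels exceed the
intensity threshold and 45.3% exceed the DFM threshold — granule-bearing
speckles whose band spectra modulate in wavelength. Rerunning across
concentrations 0–30 mg/mL shows the intensity fraction rising
monotonically while the DFM fraction plateaus above ~10 mg/mL, and
matched pigmented/albino retina scenes show the DFM highlighting only the
melanin-bearing RPE.

A command-line interface wraps the same pipeline:

```sh
inst/cli/hsoct simulate    --config cfg.yaml --seed 1 --out run/raw
inst/cli/hsoct reconstruct --in run/raw   --out run/stack
inst/cli/hsoct analyze     --in run/stack --out run/analysis
inst/cli/hsoct mie         --out run/mie
```

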