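---
title: "sPAINT simulation and analysis: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{sPAINT simulation and analysis: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(spaintr)
library(dplyr)
```

spaintr simulates and analyses spectrally-resolved PAINT (sPAINT)
experiments: single-molecule localization microscopy in which a blazed
transmission grating placed before the camera projects, for every
emitter, both its undiffracted zeroth-order image (used for spatial
localization) and its first-order diffraction spectrum onto the same
EMCCD frame. The distance between the two, here called the Z0Z1
distance, encodes the emission wavelength; with a solvatochromic dye
such as Nile Red, wavelength in turn reports the local polarity
(hydrophobicity) of the binding site. This vignette walks through the
model behind each module and the reasoning behind the defaults.

## Optical geometry

The grating has 300 grooves/mm (groove spacing $d = 10^6/300$ nm), an
8.6° blaze and sits $D = 20$ mm before the detector. First-order light
of wavelength $\lambda$ leaves the grating at
$\theta = \arcsin(\lambda / d)$ and lands
$D \tan\theta$ from the zeroth order; in 16 µm camera pixels:

```{r geometry}
predict_first_order_displacement(c(480, 580, 760))
```

580 nm light lands about 221 px from its zeroth-order spot, and the
480–760 nm detection passband spans roughly 182–293 px, which is why
the simulated detector keeps a narrow spatial strip at the top of the
frame and a deep spectral region below it. Over the passband the
grating equation is gently convex; the package linearises it through
three reference wavelengths (512.7, 581.5 and 676.5 nm, the emission
peaks of the calibration dyes), giving a dispersion of ~0.394 px/nm
with sub-0.5 px residuals:

```{r dispersion}
dispersion_from_geometry()$beta
```

## Camera model

`camera_model()` describes a back-illuminated EMCCD: 16 µm pixels at
150× magnification (106.7 nm in the sample plane), quantum efficiency
0.9, electron-multiplying gain 250, camera gain 1/9 ADU per electron,
100 ADU baseline, 10 ADU read noise, 20 Hz. The product
`gain_total()` = 0.9 × 250 / 9 = 25 ADU per emitted photon converts
fitted spot integrals back to photons. Readout is simulated as Poisson
photo-electrons, a Gamma approximation of the stochastic EM register
(which doubles the variance — the familiar excess-noise factor),
Gaussian read noise, and 16-bit quantisation with clipping.

The grating sends 60% of the light into the zeroth order; the first
order receives the remainder less a 30% transmission loss, i.e. 28% of
the emitted photons. Spectral measurements are therefore
photon-poorer, and wider, than spatial ones.

## Forward simulation

`simulate_calibration_stack()` scatters beads labelled with the three
reference dyes over the spatial strip and renders, per frame, each
bead's zeroth-order spot and its three first-order spectral blobs at
the dispersion-predicted distances. Bead x positions are drawn from
distinct 5-px columns so that, in the crowded spectral region, no two
beads' spectra overlap in the same column — a deliberate layout choice
a microscopist would mirror by picking isolated beads.

`simulate_spaint_stack()` drives a binding-site map (`site_field()`,
`luv_field()`, `fibril_field()`, `membrane_patch()`) with PAINT
kinetics: each site receives Poisson-distributed binding events at
`binding_rate_hz`, each event stays bound for an exponential
`mean_on_time_s` and spans `ceiling(t/dt)` frames. Ground truth
(positions, photons, wavelengths, event table) travels with the stack
and survives the TIFF round trip via text side-cars.

`luv_field()` places the binding sites of each ~110 nm vesicle on a
ring of its projected radius — the 2D projection of a labelled
membrane seen with ~25 nm localization error is dominated by the
equatorial band, and a ring is the simplest faithful model of it.

## Localization

Detection is a difference-of-Gaussians band-pass (PSF width 1.2 px)
followed by local-maximum selection against a robust MAD noise floor.
Each candidate is refined by Levenberg–Marquardt fitting of a
pixel-integrated 2D Gaussian plus flat background; the fitted volume
divided by `gain_total()` gives photons, and a Mortensen-style formula
(with the EMCCD excess-noise factor) gives the per-localization
precision estimate used later for rendering.

## Spectral calibration

`calibrate_stack()` localizes the beads, cuts a ±15 px intensity
profile (averaged over 3 transverse columns) around each
user-estimated Z0Z1 distance, and fits a 1D Gaussian plus offset.
Quality control discards fits with negative amplitude, centres outside
the window, or widths below 1.5 px / above 20 px. Beads with all three
dye peaks surviving enter an ordinary least-squares regression

$$Z_{01} = \beta_0 + \beta_1 \lambda + \beta_2 x + \beta_3 y,$$

whose $x$/$y$ terms absorb the grating's linear field aberration.
`wavelength_from_distance()` inverts the same equation exactly, so the
forward and inverse mappings round-trip to machine precision.

```{r calibration, eval = FALSE}
stack <- simulate_calibration_stack(n_beads = 50, n_frames = 100,
                                    seed = 1)
model <- calibrate_stack(stack)
model$recovered   # per-dye recovered wavelengths
```

## Wavelength assignment and clustering

`assign_spectra()` applies the same profile-extraction and peak-fit
machinery to experiment frames, anchoring the search window at the
calibration-predicted distance of `anchor_nm` (620 nm by default, the
middle of the probe's useful range; use the expected emission if you
know it). Localizations whose window leaves the frame, whose fit fails
quality control, or whose wavelength falls outside the passband keep
`NA` and a `qc_reason`.

`cluster_localizations()` is a DBSCAN (hand implemented on a spatial
grid index; radius 0.5 px, 10 points minimum by default) that groups
repeated bindings into structures; `cluster_summaries()` reports size,
spectra and kinetics per structure. Its diameter estimator subtracts
the localization-precision variance in quadrature from the RMS radius
(with the small-sample Bessel correction), since the observed scatter
is the true structure convolved with localization error.

## Rendering

`render_density()` deposits each localization as a discretized 2D
Gaussian of its own precision on a 10 nm grid (mass one each, so the
image integrates to the localization count). `render_spaint()`
false-colours the density with the per-pixel photon-weighted mean
wavelength on a jet scale over 560–700 nm.
`temporal_hydrophobicity_map()` smooths wavelengths with
Nadaraya–Watson kernel regression (100 nm bandwidth, 50 nm grid)
inside a moving 200-frame window advancing 16 frames per map — 0.8 s
temporal resolution at 20 Hz.

## Precision analysis

`precision_curve()` measures empirical precision the way an
experimentalist would from immobilised fiducials: group localizations
within a 4 × 4 px box (`group_fiducials()`, keeping only groups
present in at least half the frames), histogram each group's x and y
positions, fit 1D Gaussians (maximum likelihood on the binned counts)
and take the wider width — reported in nm. The (mean photons, width)
pairs are binned every 200 photons below 2,000 and every 500 above,
and the bin means are fitted with an exponential decay plus offset;
the offset is the instrument's ultimate precision — the floor that
more photons cannot buy past. A quadrature fit
$\sigma(N) = \sqrt{\sigma_\infty^2 + c/N}$ is reported alongside.

`simulate_fiducial_localizations()` generates matched synthetic data:
per-frame scatter is shot noise in quadrature with an instability
floor. The shot coefficients come from the instrument model — a 1.2 px
PSF at 106.7 nm/px gives $\approx 128/\sqrt{N}$ nm spatially, and the
~6 px spectral profile with the first order's 28%-vs-60% photon share,
divided by the 0.394 px/nm dispersion, gives $\approx 22/\sqrt{N}$ nm
spectrally. The spatial floor (6.6 nm by default) is applied along the
camera x axis only, modelling stage drift along one axis, which is
also why the analysis takes the wider of the two axis widths. The
spectral floor (1.3 nm) is one-dimensional by nature.

```{r precision, eval = FALSE}
fid <- simulate_fiducial_localizations(seed = 1)
fit <- precision_curve(fid, "spatial")
glance(fit)
autoplot(fit)
```

## Limitations

* The dispersion model is linear in $\lambda$, $x$, $y$; real gratings
  show mild curvature that the three-dye calibration cannot see.
* Spectral profiles are modelled (and fitted) as single Gaussians;
  strongly asymmetric dye spectra would bias the fitted centre.
* The simulator renders emitters as ideal Gaussians — no astigmatism,
  depth defocus, or fixed-pattern camera noise.
* DBSCAN with a 0.5 px radius assumes structures are separated by
  several pixels; touching vesicles merge.
* On-time estimation links localizations within 1 px across
  consecutive frames and does not correct for missed (sub-threshold)
  frames beyond the optional gap parameter.
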