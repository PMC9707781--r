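---
title: "Modeling foveal midget RGC spatial transfer functions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling foveal midget RGC spatial transfer functions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foveastf)
```

## The problem

Calcium imaging through an adaptive-optics scanning light ophthalmoscope
(AOSLO) can record the responses of retinal ganglion cells (RGCs) at the
living foveola while drifting gratings stimulate the centermost cones. The
measured quantity per cell is a *spatial transfer function* (STF): the
fluorescence response ΔF/F as a function of grating spatial frequency
(4–49 c/deg). The STF reflects three nested filters — the stimulation
optics, the cone apertures, and the cell's center–surround pooling of cone
signals — so inferring the receptive field (RF) requires a forward model of
all three. `foveastf` implements that forward model, the weighted
multi-start fitting procedure that recovers difference-of-Gaussians (DoG)
cone-pooling weights from measured STFs, the calcium-imaging response
metrics used to classify cells chromatically, and seeded synthetic-data
generators that emulate the measurement conditions, since the in vivo
recordings themselves are not publicly deposited.

## Forward model

**Optics.** The stimulation path is modeled as a diffraction-limited
circular pupil (6.7 mm, 561 nm) plus residual defocus expressed as the
OSA/ANSI Zernike (2, 0) coefficient, `c = D * a^2 / (4 * sqrt(3))` with `a`
the pupil radius in mm (the diopter↔coefficient convention is not uniquely
standardized; this is the common choice and is used consistently). The PSF
is `|FT(pupil function)|^2` on a 0.0012-deg grid — fine enough to resolve
the 208.4 c/deg incoherent cutoff — and the MTF is the magnitude of its
Fourier transform. The analytic circular-aperture MTF serves as an
independent oracle in the tests. Arbitrary Zernike term lists are accepted
for "physiological optics" runs; since the animal's measured wavefronts are
not published, such runs take user-supplied or synthetic wavefronts, and a
Gaussian-blur reference family (`gaussian_optics()`) covers the
demonstration of how natural optics reshape STFs.

One physical caveat: the familiar claim "more defocus, lower MTF" holds
only below the first transfer null. Beyond it, defocus phase reversals
create spurious resolution (e.g. at 0.15 D and 40 c/deg on a 6.7-mm
pupil the MTF is higher than at 0.10 D). The package's monotonicity tests
therefore restrict to the pre-null regime (0–0.1 D over 4–28 c/deg, and
0–0.2 D below 20 c/deg).

**Cone mosaic.** A quasi-hexagonal mosaic with peak density 270,200
cones/mm², L:M:S = 0.48:0.48:0.04, random L/M assignment, quasi-regular S
packing, and no S-free zone. Only the peak density is well constrained, so
the radial falloff defaults to an interpolated profile reaching
~150,000 mm⁻² at 0.65 deg and is configurable by table. Generation is by
hexagonal lattice, radial density warping, positional jitter
(σ = 0.12 × local spacing) with minimum-distance rejection, rather than an
iterative mosaic algorithm: acceptance is by the measurable invariants
(local density within 10% of target in 10-μm annuli; 6-neighbor spacing
within 5% of `sqrt(2/(sqrt(3) d))`; class fractions within ±0.02). The
single nearest-neighbor distance is biased low under jitter, so hex spacing
is estimated as the mean distance to the six nearest neighbors. Inner
segment diameters default to the local hex spacing (measured diameters are
not deposited); apertures are Gaussian with characteristic radius
`0.204 * sqrt(2) * D` — the conventional reading of the aperture-fraction
factor. Cone spectra are Govardovskii A1 templates at macaque peaks
(L 561, M 530, S 430 nm; configurable, since the cited source values are
not printed), filtered by synthetic lens and macular-pigment templates
with the qualitative shape of published young-eye spectra (replaceable by
user tables; files are labeled synthetic).

**Stimulus.** Drifting monochromatic gratings: 561 nm (5 nm FWHM), 100%
contrast, 6 Hz drift, 25.3 Hz refresh, 666 ms (4 cycles, 17 frames of
39.5 ms), 0.7-deg field at 0.005 deg/pixel, 1.29 mW/cm² mean irradiance.
Frame count is rounded to nearest (17), preserving the 4 cycles. Scenes are
stored in separable form — spatial frames × one spectral profile — which is
exact for every stimulus in scope and keeps the pipeline fast. Horizontal
orientation means bars vary along y. Chromatic flicker stimuli are built by
a silent-substitution solver: the cone-contrast matrix of the LED primaries
(420/530/660 nm Gaussians around a half-maximum background) is solved for
modulations in the null space of the silenced classes, scaled to the
largest feasible amplitude under the per-primary gamut `|m| ≤ 1` (the
in vivo allocation rule is unpublished; scaling the projected
target-gradient direction is this package's choice). The solver is
verified by its defining nulling property rather than by reproducing the
printed in vivo modulation depths, which depend on unpublished LED
calibrations.

**Excitations, modulations, pooling.** Per frame, the scene is convolved
with the PSF (frequency-space, on a padded grid, padding at the background
level), weighted by each cone's effective quantal efficiency, integrated
over the Gaussian aperture (a second frequency-space convolution, cones
grouped in 0.05-μm aperture bins, bilinear sampling at cone positions), and
scaled by the frame duration. No Poisson noise and no fixational eye
motion: the recordings being emulated were made under anesthesia with
stabilized stimuli. Contrast conversion is `R = (E − E0)/E0`. The RGC
response is the instantaneous weighted sum
`Σ Wc R − Σ Ws R` with Gaussian center/surround weight profiles (or a
single-cone center); there is no temporal filtering or center–surround
delay, because single-temporal-frequency amplitude data cannot constrain
them. A sinusoid at the fixed 6-Hz drift frequency (plus an offset term) is
fitted by linear least squares to the pooled response; its amplitude A(ω)
is the model STF.

Because pooling is linear and the sinusoid fit is linear, the package
precomputes each cone's complex quadrature amplitude per frequency once
(`stf_model_context()`); any DoG weight vector's STF is then a complex
linear combination. This is mathematically identical to rerunning the full
chain per candidate parameter set (a test verifies the equivalence to
1e−10) and is what makes 512-start fitting tractable.

## Fitting procedure

The objective is the weighted RMSE
`sqrt(1/N Σ β(ω)/ε(ω) [STFm − STFΔF/F]²)`, with β the linear
high-frequency boost (0.1 at 4.7 c/deg to 1.0 at 49 c/deg, clamped) and ε
the per-frequency SEM, floored at `1e-3 × max|ΔF/F|` so error-free
synthetic data cannot produce infinite weights (the flooring is flagged).
β multiplies the squared residual, exactly as displayed in the source
formula. STFs that dip below zero are shifted so their minimum is zero
before fitting (overestimated-background correction), and the shift is
recorded.

Optimization is multi-start bounded local search (`optim` L-BFGS-B) in
log10 parameter space: `kc, ks ∈ [1e-4, 1e4]`, radii from a quarter of the
cone spacing to 1 deg, `rs ≥ rc` *not* enforced — foveolar surrounds can be
nearly coextensive with centers. Starts are log-uniform within bounds from
a seeded generator; 512 starts by default; ties go to the first minimum
found. Because the multi-cone amplitude is exactly invariant under swapping
(kc, rc) with (ks, rs), fits are canonicalized to `rc ≤ rs` after
optimization. Fits are repeated over a 9-point grid of candidate RF center
positions spanning a 40-μm square (the anatomical uncertainty of the RF
center), and the minimum-RMSE position wins. Scenario and residual-defocus
sweeps call this per grid cell; the default defocus grid is 0–0.1 D in
0.01 D steps plus the canonical 0.067 D. Cross-validation fits on one
session and evaluates the same objective on another.

Derived statistics are `rc/rs`, `ks/kc` and the integrated
surround/center ratio `(ks/kc)(rs/rc)²`; for single-cone fits the
equivalent center radius is the center cone's aperture radius.

`predict_physiological_stf()` swaps the stimulation optics for supplied
physiological optics (e.g. a wavefront at a 2.5-mm pupil, or Gaussian
blur), drives a 100%-contrast achromatic grating, and fits a plain
unweighted descriptive DoG curve to the predicted STF — the analysis
convention of classical in vivo work. A useful subtlety: a mild Gaussian
blur can have a *better* MTF than defocused AO optics at low frequencies,
so "physiological blur lowers the peak" is asserted only for blur radii
(≥ 0.02 deg) representative of natural pupils, and monotonically along
increasing blur.

## Calcium-imaging metrics

Flicker responses: the trace is Hann-windowed, Fourier-transformed, and the
amplitude at the stimulus frequency is compared with the 0.32–1.08 Hz noise
band — SNR = (signal − mean noise)/SD of noise, a d′ equivalent. The SD is
the sample (n−1) standard deviation, an unstated detail chosen here. The
sign is flipped for responses more than 90° out of phase (OFF); the phase
reference is an identically windowed sinusoid, which makes the comparison
exact under windowing. Grating responses: ΔF/F = (signal − background)/
(signal at 17 c/deg), with first-order error propagation
`sqrt((σS² + σB²)/S17² + (S − B)² σS17²/S17⁴)` (validated against
Monte-Carlo propagation to 2%). Cone weights divide each class's SNR by its
stimulus modulation and normalize to unit absolute sum, signs preserved.
Classification applies the |SNR| ≥ 2 cutoff: opposite-signed significant L
and M (or a significant isoluminant L−M response) without S → L-M/M-L
opponent; S only → S-ON/OFF; luminance (or a single cone class) only →
luminance-ON/OFF; opponency plus S → mixed. How a barely-significant S
response interacts with opponency is unspecified in the source; here any
significant S on top of opponency is "mixed".

## Synthetic data and what passing tests mean

The generators emulate the study conditions: 14 log-spaced frequencies over
4–49 c/deg (the measured design is not listed; log spacing is this
package's default), three sessions with independent Gaussian per-frequency
noise at 10% of the peak ΔF/F (an eyeball-level match to the published
session scatter, used only as a default), SEM across sessions, an optional
negative offset to exercise the offset rule, and 90-s flicker traces at
0.15–0.2 Hz with white noise and drift. They deliberately do *not*
simulate GCaMP kinetics, eye-motion residuals, imaging-laser crosstalk,
correlated (non-Gaussian) session noise, or orientation anisotropies — so
parameter-recovery results bound what is attainable under idealized noise,
not under all real-data pathologies.

The achromatic-midget simulation wires each interior cone of a ~2,400-cone
hexagonal disk to its 6 neighbors and asks how often at least 5 (or all 6)
surround cones match the center class under random class assignment. Its
closed-form oracle is `Σ p_t·p_t⁶` and `Σ p_t(p_t⁶ + 6p_t⁵(1−p_t))`; at
0.48/0.48/0.04 the thresholded expectation is 8.81% ("approximately 9%").
The supplement prints "approximately 1.5%" for the all-6 fraction while the
closed form gives 1.17%; the counting convention there is underspecified
(denominator, edge handling), so the oracle — not 1.5% — is the test value.
All center cones, including S-centered ones, count in the denominator;
excluding them changes the fractions by less than 0.4 percentage points.

## Numerical choices and problem sizes

* PSF grid 0.0012 deg/px with the pupil array padded 8× — MTF resolution
  0.8 c/deg; the radial MTF table carries an exact unity DC sample.
* Scene convolutions run on a power-of-two padded grid (≥1.5× the field),
  padded at the background level; the PSF is binned onto the 0.005-deg
  stimulus raster before use so the fine pupil transform is never
  undersampled.
* Verification against the closed-form DoG × MTF × aperture product uses
  error normalized by the curve peak (the pointwise ratio diverges at the
  DoG cancellation null that realistic bandpass cells place in-band), and
  moment-matched effective radii/densities (`analytic_stf_oracle()`):
  against the exact discrete plane-wave sum the image pipeline is accurate
  to ≤1% of peak, and the remaining continuum gap is the real effect of
  eccentricity-dependent density on an inhomogeneous mosaic.
* Tests and the worked examples use a 0.3-deg mosaic patch (~900 cones)
  and 48–64 optimizer starts per position; these sizes recover noise-free
  parameters to well under the stated tolerances while keeping a full test
  run in minutes. The `fit_stf()` default remains 512 starts, and mosaics
  up to the full 1.3-deg extent are supported.
* Degenerate inputs: zero-extent mosaics return empty tibbles; zero SEMs
  are floored; `rho = 0` Gaussian optics is a delta PSF; all-negative STFs
  offset to zero minimum.

## A short tour

```{r tour, eval = FALSE}
mosaic <- synthesize_cone_mosaic(extent_deg = 0.3, seed = 1)
optics <- compute_psf_mtf(pupil_spec(6.7, 561, defocus_D = 0.067))
ctx <- stf_model_context(mosaic, optics)

truth <- build_rf_weights(mosaic, kc = 2, ks = 0.05, rs_deg = 0.06,
                          scenario = "single-cone")
data <- synth_stf_dataset(truth, ctx, sessions = 3, noise_frac = 0.1,
                          seed = 1)
fit <- fit_stf(data$averaged, ctx, scenario = "single-cone",
               n_starts = 64, seed = 1)
tidy(fit); glance(fit); derived_stats(fit)
autoplot(fit)

physio <- predict_physiological_stf(fit, gaussian_optics(0.04), ctx)
autoplot(physio)
```

## Known limitations

The lens/macular spectra and the density falloff are synthetic templates,
not per-animal measurements; the diopter↔Zernike convention and the
aperture factor follow the conventional readings noted above; temporal
dynamics (GCaMP kinetics, center–surround delay) are out of scope by
design; and reproducing the in vivo population values (cell-type
proportions, the 0.067 D mean fitted defocus as a data result, the
published Rc/Rs, Ks/Kc and integrated-ratio means) is impossible without
the unreleased recordings — those numbers appear here only as defaults or
synthetic-scenario settings.
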