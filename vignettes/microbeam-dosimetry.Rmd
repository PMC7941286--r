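---
title: "Microbeam dosimetry at a bending-magnet beamline: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microbeam dosimetry at a bending-magnet beamline: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbdosim)
```

## What this package models

Microbeam radiation therapy (MRT) irradiates tissue with arrays of
quasi-parallel X-ray beams tens of micrometres wide. The therapeutic
rationale rests on the peak-to-valley dose ratio (PVDR): tumour cells in
the beam paths receive tens of Gy while the tissue between beams — the
valley — receives a small scatter-dominated dose that normal tissue
tolerates. `mbdosim` implements the dosimetric simulation and analysis
chain for the first microbeam cell-irradiation experiment at a
medium-energy bending-magnet beamline: a 2.4 GeV storage ring with a
1.45 T dipole, a tungsten multi-slit collimator (MSC) producing 50 µm
beams at 400 µm pitch, and plated melanoma cell cultures scanned
vertically through the fan beam.

The chain has five physics stages, each an independently testable module:

1. **Spectrum** — the vertically integrated Schwinger dipole spectrum,
   filtered by 2.0 mm beryllium and 3.5 mm aluminium.
2. **Collimator geometry** — closed-form ray tracing of tungsten path
   lengths through the periodic lamella comb for the divergent source.
3. **Monte Carlo transport** — simplified photon transport with voxel
   dose scoring in the water layer holding the cells.
4. **Virtual scanning** — superposition of vertically stepped static
   fields, mimicking the constant-speed stage translation.
5. **Analysis** — profile extraction, peak detection, peak/valley doses
   and PVDR with uncertainties.

Alongside these sit the radiochromic-film workflow (net optical density,
calibration, dose maps), the cell-survival statistics, and seeded
synthetic-data generators that stand in for the beamline and the cell
lab so that every stage has a recovery test against known ground truth.

## Spectrum model

The unfiltered flux follows the universal dipole spectral shape
$G_1(y) = y\int_y^\infty K_{5/3}(x)\,dx$ with $y = E/E_c$ and critical
energy $E_c = 0.665\,E^2[\mathrm{GeV}]\,B[\mathrm{T}]$ keV (5.55 keV
here). Flux per keV is obtained from the standard
photons/s/mrad/0.1%-bandwidth form. The default grid is 5–150 keV in
0.5 keV steps: it resolves the filtered peak near 25 keV, and the flux
outside that range is negligible after 3.5 mm of aluminium.

**Mean energy is flux-weighted** (photon-number weighting), matching the
photon-counting transport that consumes the spectrum. The filtered
flux-weighted mean is about 28.2 keV. The energy-fluence (power)
weighted alternative, available as `mean_energy(sp, "power")`, gives
30.0 keV; reported beamline figures of "about 30 keV" are consistent
with that convention. Both are exposed; the package reports the
flux-weighted value.

Vertical angular dependence of the spectrum is ignored: the 0.175 mrad
vertical acceptance is small, and after the aluminium filtration the
residual spectral variation across it is far below the other model
uncertainties.

## Attenuation data

Mass attenuation tables for beryllium, aluminium, tungsten, water and
air (5–150 keV, ≥40 log-spaced nodes, tungsten L/K edges as paired
nodes) ship as delimited text under `inst/extdata/materials/`. Totals
are anchored on published tabulated values; the incoherent partial is
the free-electron Klein–Nishina cross section scaled by Z/A — the same
model the transport uses — the coherent partial is a $Z^2/E^2$
parametrization calibrated on water at 30 keV, and the photoelectric
partial is the positivity-constrained residual, so the partials sum to
the total by construction. Lookups interpolate log-log. This keeps the
package self-contained; the property tests pin the tables to frozen
reference values at 10/30/60/100 keV within 2%.

## Collimator and source geometry

All geometry lives in one beamline frame (origin at the source, z along
the beam). The MSC is an ideal periodic comb of 8 mm-deep tungsten
lamellae; the tungsten path of a ray is computed in closed form from the
open-interval measure crossed between its entrance and exit abscissae,
and is verified against a 0.1 µm step-march oracle to better than
0.5 µm. Two consequences of the 7 mrad horizontal divergence fall out
directly:

* off-axis beams narrow, because an oblique ray walks
  $d\,x/L \approx 8\,\mathrm{mm} \times x/15.5\,\mathrm{m}$ across the
  comb — about 8 µm at the ±15 mm acceptance edge, giving ~42 µm
  effective width against 50 µm on axis;
* the projected pitch and widths at the sample carry the geometric
  magnification $(15.5 + 0.3)/15.5 \approx 1.019$. Outputs are labelled
  nominal (MSC-plane) or projected.

Lamella manufacturing error, yaw misalignment and slit-edge scattering
are not modelled; the asymmetric single-beam edge feature seen on
high-resolution imagers is therefore outside this model's reach.

## Monte Carlo transport model

Histories are sampled from the filtered spectrum and a Gaussian source
(horizontal divergence 7 mrad FWHM, horizontal source size 0.1 mm RMS;
the vertical coordinate is drawn directly from the measured 1.5 mm FWHM
envelope at the sample). Transport is deliberately simplified relative
to a general-purpose code, and each simplification is a documented
lever:

* **Deterministic attenuation (implicit capture)** through tungsten and
  the 30 cm air column: no collimator scatter, no analogue absorption.
  This is the main variance-reduction device — the valley signal would
  otherwise be dominated by the vanishing probability of lamella
  penetration (8 mm of tungsten at 30 keV transmits < 1e-30).
* **Slit-window importance sampling**: horizontal positions at the MSC
  are drawn from the true Gaussian restricted to margin-widened slit
  windows (25 µm margins cover the penumbra and partial-depth
  clipping), with the exact restriction probability Q as a constant
  weight. One sampled history therefore stands for 1/Q full-fan
  histories; the equal-weight scheme adds no weight variance.
* **Forced interactions** in the slab: each chord interacts with
  probability $1 - e^{-\mu l}$ carried as weight, the site drawn from
  the truncated exponential. Branches follow the partial cross
  sections: photoelectric absorbs locally; incoherent scattering
  (free-electron Klein–Nishina, sampled by rejection) deposits the
  electron energy locally and tracks the scattered photon; coherent
  scattering (Thomson × independent-atom form factor for water)
  deflects without energy loss. Chains terminate at 5 keV (deposited
  locally), at a 1e-12 weight floor, or after 10 generations.
* **Kerma approximation**: secondary electrons are not transported.
  CSDA ranges at these energies (≲20 µm in water) are comparable to one
  5 µm lateral voxel; a configurable Gaussian blur (default σ = 5 µm)
  approximates their lateral spread. The approximation slightly
  sharpens the peaks relative to full electron transport; it cannot
  move dose into the valley centre 150–200 µm away.

Energy is scored depth-integrated over the 1 mm water layer in
5 µm × 100 µm voxels — 5 µm on the horizontal, microbeam-modulated axis,
the only resolution-critical direction. Every run records its seed,
sampled and effective history counts, and energy bookkeeping (scored ≤
launched is asserted in tests).

### The scatter domain is the culture vessel

The cells sit in a well of a standard 24-well polystyrene plate, and the
reference full-physics simulation included that vessel. Polystyrene is
water-equivalent to within a few percent at these energies, so the
default phantom wraps the scored 1 mm water layer in 1 mm
water-equivalent entrance and exit layers (nominal wall thickness) and
bounds the slab laterally at ±8 mm, the radius of a standard well. These
choices matter: with a bare 1 mm slab the valley loses roughly half its
scatter sources and the PVDR roughly doubles; widening the lateral
domain from 6 mm to 12 mm moves the PVDR by about ±5%. The defaults are
fixed from the nominal vessel dimensions, not fitted; all are exposed in
`phantom_spec()` and the bare-slab configuration remains one argument
away.

## Virtual scanning and absolute dose

Scanning the sample vertically at speed $v$ through a beam of height $h$
(FWHM) at dose rate $\dot D$ delivers $D = (h/v)\,\dot D$ — with the
measured 70 Gy/s, 1.5 mm and 1.638 mm/s this is 64.1 Gy, the "about
65 Gy" peak dose of the experiment. The simulated scanned field is the
superposition of the static field at 100 µm vertical source steps. The
scan range spans the sample height **plus the full vertical extent of
the static grid**: the stage physically travels until the beam clears
the sample, so every sample point integrates the complete static field,
scatter halo included. Truncating the range at a few envelope sigmas —
a natural-looking shortcut — silently drops the halo tails and
underestimates the valley by ~25%.

Absolute dose is anchored by rescaling the simulated field so the
central-beam ±20 µm peak equals the measured scan dose; the Monte Carlo
provides shape, the ionization-chamber-traceable dose rate provides
scale, and the PVDR is invariant under the rescaling. The 70 Gy/s is
treated as the peak-position dose rate at the sample, consistent with
the ~65 Gy peak.

## Profile analysis and uncertainties

Profiles average the grid vertically (presets: 0.5 mm for imager-like
profiles, 2 mm for film-like ones). Peaks are local maxima above half
the profile maximum, refined by three-point parabolic interpolation —
with plateau (flat-top) runs collapsed to their midpoint first, since a
rectangular beam top otherwise yields one candidate per voxel. Peak dose
is the mean over ±20 µm around each centre; valley dose is the mean over
the central 100 µm between adjacent centres (the window is
config-exposed: symmetric, penumbra-free, suited to the 400 µm pitch).
The headline PVDR uses the central microbeam, whose valley is highest —
the conservative choice, since the valley falls towards the field edges;
a per-beam table accompanies it.

Uncertainties need care in two places. First, per-voxel standard errors
come from independent batches, but valley voxels receive so few,
strongly weighted deposition events that per-voxel variance estimates
are biased low, and after the scan superposition neighbouring rows are
built from the same static events and are nearly fully correlated.
Region statistics for scanned fields are therefore computed from
batch-aggregated profiles with jackknife-over-batches errors, and
`horizontal_profile()` treats scanned rows as correlated when averaging.
Second, the 1/√N convergence check extrapolates the peak-region relative
standard error measured across a hundredfold span of effective histories
to the reference history count of 3×10^10.

## Film dosimetry and its emulation

Film readout is single-channel: net optical density
$\mathrm{netOD} = \log_{10}(I_0/I)$, clipped at zero, with saturated
pixels flagged. Calibration uses the monotone rational model
$D = a\,\mathrm{netOD} + b\,\mathrm{netOD}^{2.5}$ (the exponent is
config-exposed; no functional form is canonical, and this one is linear
in its coefficients and strictly monotone for positive coefficients, so
it inverts cleanly). Dose maps never extrapolate outside the film's
dynamic range — EBT3 (0.1–20 Gy, ~25 µm resolution) and HD-V2
(10–1000 Gy, ~5 µm) are complementary by design: HD-V2 ranges the 65 Gy
peaks, EBT3 resolves the sub-Gy valleys. The synthetic film generator
runs the chain backwards — dose pattern, inverse calibration, film +
readout point-spread function, multiplicative and additive intensity
noise, 16-bit quantization — and returns its ground truth. Its PSF makes
the resolution contrast testable: a 10 µm stripe survives the HD-V2
blur but not the EBT3 blur. Scanner lateral-response correction,
RGB multichannel dosimetry and darkening kinetics are out of scope; the
synchrotron calibration doses of the original experiment are not public,
so calibration sets are synthetic and labelled as such.

## Cell-survival statistics

Survival is the ratio of treated to control mean counts with first-order
error propagation of the replicate SEMs. The generator draws lognormal
replicates (CV 0.1 by default) around the control mean and around
control × survival — multiplicative noise is the natural model for cell
counts, and a CV of 0.1 makes triplicate experiments capable of the
very small p-values the study design reports; only SEM bars, not raw
counts, are public, so the dispersion is an assumption and is
config-exposed. The default significance test is the pooled (Student)
two-sample t-test on log counts: the log transform matches the
multiplicative noise and equalizes group variances, and with n = 3 the
pooled test retains the degrees of freedom that Welch's correction
gives away — under Welch (df ≈ 2) a survival-0.2 effect at CV 0.1 yields
p ≈ 0.01, and a 3-vs-3 permutation test cannot go below 0.05, so
neither can produce p-values of order 10^-4 from triplicates. Welch,
raw-scale and permutation variants are available by flag. Type-I error
of the default is verified by simulation under the null.

## What the synthetic generators do and do not show

The generators emulate the *statistical structure* the analysis assumes:
comb dose patterns with envelopes, film PSF/noise/quantization,
lognormal replicate counts. Passing recovery tests shows the analysis
chain is correct and calibrated on data of that structure. It does not
show that real films (with spatial nonuniformity, scanner artefacts,
energy-dependent response) or real cell counts (with plating losses and
correlated handling effects) obey those models — the published cell
percentages (20.5%, 23.5%) and the film valley band (0.5–0.75 Gy) rest
on unpublished raw data and are emulated, not reproduced.

## Numerical choices and problem sizes

* Energy grid 0.5 keV; log-log interpolation of attenuation data;
  trapezoidal spectral quadrature; inverse-CDF spectral sampling.
* Voxels are half-open bins, positions are bin centres, units are
  encoded in field names (`pitch_um`, `speed_mm_s`).
* One master seed per run; per-batch child seeds drawn from it; every
  artifact records seed and history counts, and a fixed seed reproduces
  results bit-for-bit.
* The test suite runs Monte Carlo cases at 2×10^4–10^6 sampled
  histories (about 10^6–6×10^7 effective) so the default suite finishes
  in a few minutes; the acceptance script uses 6×10^6 sampled histories
  (about 3.5×10^8 effective), chosen so the central-beam PVDR carries a
  ~2% jackknife standard error.

## Known limitations

* No collimator scatter, fluorescence, bound-Compton or Doppler
  corrections, polarization, or explicit electron transport; the
  simplified model's central-beam PVDR sits below a full-physics
  treatment of the same geometry by roughly 10%, within the combined
  modelling and statistical uncertainties the analysis reports.
* The vessel representation (flat adjacent water-equivalent walls,
  ±8 mm lateral bound) brackets, but does not resolve, the true
  well-plate geometry; the PVDR sensitivity to it is of order ±15%
  across plausible configurations.
* The ideal-comb collimator cannot reproduce manufacturing or alignment
  artefacts.
* Film emulation is grayscale single-channel with a Gaussian PSF.
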