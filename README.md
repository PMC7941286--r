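# mbdosim

Dosimetry simulation and analysis for synchrotron **microbeam radiation
therapy (MRT)** at a bending-magnet beamline. MRT splits an intense
X-ray fan into an array of quasi-parallel beams tens of micrometres
wide; tissue in the beam paths receives a high *peak* dose while the
tissue between beams receives a low, scatter-dominated *valley* dose.
The ratio of the two — the **peak-to-valley dose ratio (PVDR)** — is the
central dosimetric figure of merit, because a high PVDR is what lets
normal tissue tolerate peak doses of tens of Gy.

`mbdosim` is written for physicists and radiobiologists commissioning or
analysing microbeam irradiation experiments at medium-energy
bending-magnet sources. It models, end to end:

* the **bending-magnet spectrum** via the vertically integrated
  Schwinger formula — flux per keV proportional to
  `G1(E/Ec) = (E/Ec) ∫ K_{5/3}(x) dx`, with critical energy
  `Ec = 0.665 E²[GeV] B[T]` keV — filtered through 2.0 mm Be + 3.5 mm Al
  using packaged mass-attenuation tables;
* the **tungsten multi-slit collimator** (50 µm slits, 400 µm pitch,
  8 mm depth) by closed-form ray tracing for the divergent source,
  including the narrowing of off-axis beams;
* a **simplified Monte Carlo photon transport** (deterministic
  collimator/air attenuation, slit-window importance sampling, forced
  interactions, Klein–Nishina Compton, form-factor Rayleigh, kerma
  approximation) scoring dose in 5 µm × 100 µm voxels in the 1 mm water
  layer that holds the plated cells, inside water-equivalent
  culture-vessel walls;
* the **scanned field** produced by translating the sample vertically
  through the 1.5 mm (FWHM) fan at constant speed, with the analytic
  anchor `dose = beam_height / speed × dose_rate`;
* **profile / PVDR analysis** (±20 µm peak regions, 100 µm central
  valley windows, jackknife uncertainties), **radiochromic film
  dosimetry** (netOD, monotone calibration, dose maps, EBT3 / HD-V2
  characteristics), **cell-survival statistics** for irradiated vs
  control replicate counts, and **seeded synthetic-data generators**
  for film images and cell-count tables with ground truth.

## Worked example

Simulate the standard configuration (2.4 GeV / 1.45 T ring, 20 central
microbeams, 70 Gy/s dose rate, 1.638 mm/s scan speed) and analyse the
scanned field at the cell position:

```r
library(mbdosim)

sp <- beamline_spectrum()
cat(sprintf("Filtered mean energy: %.1f keV\n", mean_energy(sp)))
cat(sprintf("Scan dose on sample : %.1f Gy\n", surface_dose(1.5, 1.638, 70)))

static <- run_static_field(transport_config(n_histories = 1e6, seed = 1))
field  <- normalize_absolute(scanned_field(static), 65)
res    <- analyze_field(field)
print(res$pvdr_result)

report <- cell_report(synth_cell_counts(synth_cell_spec(seed = 1)))
print(report, digits = 3)
```

```
Filtered mean energy: 28.2 keV
Scan dose on sample : 64.1 Gy
PVDR: 107.2 +- 3.7 (peak 65 +- 1.4, valley 0.606 +- 0.011)
  timepoint_h survival_fraction    sem  p_value
1          24             0.223 0.0170 3.87e-05
2          72             0.234 0.0126 1.07e-05
```

Reading the output: the flux-weighted mean of the filtered spectrum is
28.2 keV (the power-weighted convention gives 30.0 keV; see the
vignette). The scan formula turns the measured 70 Gy/s dose rate into a
64.1 Gy dose on the sample — the "approximately 65 Gy" peak dose the
field is anchored to. The Monte Carlo scanned field then shows a
central-beam PVDR of ~107 ± 4 at this run size, i.e. a valley dose of
~0.6 Gy between 65 Gy peaks — low enough that cells between beams sit
far below any cytotoxic dose. The synthetic triplicate cell counts,
generated at the survival fractions such an irradiation produced,
recover those fractions (~20–24%) with p-values of order 10⁻⁴–10⁻⁵.

`run_pipeline(default_config(seed = 1))` drives the same chain end to
end and, given an output directory, writes every intermediate artifact
(spectrum, dose grids, profile, JSON summary, provenance log) in
re-loadable delimited-text formats.

## Package layout

| Area | Files |
| --- | --- |
| Spectrum & attenuation | `R/spectrum.R`, `R/materials.R`, `inst/extdata/materials/` |
| Collimator geometry | `R/geometry.R` |
| Monte Carlo transport | `R/transport.R`, `R/dose_grid.R` |
| Scanning & normalization | `R/scan.R` |
| Profile / PVDR analysis | `R/analysis.R` |
| Film dosimetry | `R/film.R` |
| Cell statistics | `R/cells.R` |
| Synthetic generators | `R/synthetic.R` |
| Configuration & pipeline | `R/pipeline.R` |

The methods vignette (`vignettes/microbeam-dosimetry.Rmd`) documents the
physics models, their assumptions and simplifications, the default
parameters and why they were chosen, and what the synthetic-data tests
do and do not demonstrate about real beamline data.
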