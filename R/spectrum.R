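#' @title Bending-magnet spectrum synthesis
#' @description Vertically integrated Schwinger spectrum for a dipole
#'   (bending-magnet) synchrotron source, filter attenuation, spectral
#'   summaries and seeded spectral sampling.
#' @name spectrum
NULL

#' Storage-ring parameters of the source
#'
#' @param electron_energy_gev electron energy in GeV.
#' @param magnetic_field_t dipole magnetic field in tesla.
#' @param ring_current_ma stored beam current in mA.
#' @export
ring_parameters <- function(electron_energy_gev = 2.4,
                            magnetic_field_t = 1.45,
                            ring_current_ma = 160) {
  vals <- c(electron_energy_gev, magnetic_field_t, ring_current_ma)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("ring parameters must all be strictly positive")
  }
  structure(list(electron_energy_gev = electron_energy_gev,
                 magnetic_field_t = magnetic_field_t,
                 ring_current_ma = ring_current_ma),
            class = "ring_parameters")
}

#' Critical energy of a bending magnet
#'
#' `E_c = 0.665 * E[GeV]^2 * B[T]` keV, the energy dividing the emitted
#' power in half.
#'
#' @param ring a [ring_parameters()] object.
#' @return critical energy in keV.
#' @export
critical_energy <- function(ring) {
  stopifnot(inherits(ring, "ring_parameters"))
  0.665 * ring$electron_energy_gev^2 * ring$magnetic_field_t
}

#' Photon spectrum container
#'
#' @param energy_kev strictly ascending energy grid in keV.
#' @param flux_density non-negative flux density, photons/s/keV.
#' @export
photon_spectrum <- function(energy_kev, flux_density) {
  stopifnot(length(energy_kev) == length(flux_density),
            length(energy_kev) >= 2)
  if (is.unsorted(energy_kev, strictly = TRUE)) {
    stop("energy grid must be strictly ascending")
  }
  if (any(flux_density < 0) || any(!is.finite(flux_density))) {
    stop("flux density must be finite and non-negative")
  }
  structure(list(energy_kev = as.numeric(energy_kev),
                 flux_density = as.numeric(flux_density)),
            class = "photon_spectrum")
}

#' Default energy grid: 5 to 150 keV in 0.5 keV steps
#' @export
default_energy_grid <- function() seq(5, 150, by = 0.5)

# G1(y) = y * integral_y^inf K_{5/3}(x) dx, the universal (vertically
# integrated) spectral shape of dipole radiation
schwinger_g1 <- function(y) {
  vapply(y, function(yy) {
    if (yy <= 0) return(0)
    yy * stats::integrate(function(x) besselK(x, 5 / 3), yy, Inf,
                          rel.tol = 1e-9)$value
  }, numeric(1))
}

#' Unfiltered bending-magnet spectrum (vertically integrated)
#'
#' Schwinger formula integrated over the vertical opening angle:
#' `2.457e13 * E[GeV] * I[A] * G1(E/Ec)` photons/s/mrad/0.1%bw, converted
#' to photons/s/keV over the stated horizontal acceptance.
#'
#' @param ring [ring_parameters()].
#' @param energy_kev ascending, positive energy grid (keV).
#' @param horizontal_acceptance_mrad horizontal fan accepted, mrad.
#' @return a [photon_spectrum()].
#' @export
bending_magnet_spectrum <- function(ring,
                                    energy_kev = default_energy_grid(),
                                    horizontal_acceptance_mrad = 1.935) {
  stopifnot(inherits(ring, "ring_parameters"))
  if (length(energy_kev) == 0) stop("empty energy grid")
  if (any(energy_kev <= 0)) stop("energy grid must be positive")
  ec <- critical_energy(ring)
  per_01bw <- 2.457e13 * ring$electron_energy_gev *
    (ring$ring_current_ma / 1000) * schwinger_g1(energy_kev / ec)
  flux_per_kev <- per_01bw / (0.001 * energy_kev) *
    horizontal_acceptance_mrad
  photon_spectrum(energy_kev, flux_per_kev)
}

#' Apply filter attenuation to a spectrum
#'
#' @param spectrum a [photon_spectrum()].
#' @param filters list of [filter_element()]; empty list is the identity.
#' @export
apply_filters <- function(spectrum, filters) {
  stopifnot(inherits(spectrum, "photon_spectrum"))
  trans <- filter_transmission(filters, spectrum$energy_kev)
  photon_spectrum(spectrum$energy_kev, spectrum$flux_density * trans)
}

trapz <- function(x, y) {
  sum(diff(x) * (y[-length(y)] + y[-1]) / 2)
}

#' Mean energy of a spectrum
#'
#' Flux-weighted (photon-number-weighted) by default, matching the
#' photon-counting transport input; `weighting = "power"` gives the
#' energy-fluence-weighted alternative.
#'
#' @param spectrum a [photon_spectrum()].
#' @param weighting `"flux"` or `"power"`.
#' @return mean energy in keV (trapezoidal quadrature).
#' @export
mean_energy <- function(spectrum, weighting = c("flux", "power")) {
  stopifnot(inherits(spectrum, "photon_spectrum"))
  weighting <- match.arg(weighting)
  e <- spectrum$energy_kev
  f <- spectrum$flux_density
  if (weighting == "power") f <- f * e
  denom <- trapz(e, f)
  if (denom <= 0) stop("spectrum has zero integrated flux")
  trapz(e, e * f) / denom
}

#' Sample photon energies from a spectrum
#'
#' Inverse-CDF sampling on the (piecewise-constant) binned flux density.
#' Uses the current R RNG state unless `seed` is given.
#'
#' @param spectrum a [photon_spectrum()].
#' @param n number of samples, >= 1.
#' @param seed optional integer seed for reproducibility.
#' @return numeric vector of energies in keV.
#' @export
sample_energies <- function(spectrum, n, seed = NULL) {
  stopifnot(inherits(spectrum, "photon_spectrum"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  e <- spectrum$energy_kev
  f <- spectrum$flux_density
  if (sum(f) <= 0) stop("degenerate spectrum: all-zero flux")
  # bin probabilities from trapezoid areas; uniform within each bin
  w <- diff(e) * (f[-length(f)] + f[-1]) / 2
  if (sum(w) <= 0) {
    # single nonzero node: return that energy
    return(rep(e[which.max(f)], n))
  }
  bin <- sample.int(length(w), n, replace = TRUE, prob = w)
  stats::runif(n, e[bin], e[bin + 1])
}

#' Write a spectrum as two-column delimited text
#'
#' @param spectrum a [photon_spectrum()].
#' @param path output file.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "photon_spectrum"))
  utils::write.table(
    data.frame(energy_keV = spectrum$energy_kev,
               flux_density = spectrum$flux_density),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a spectrum written by [write_spectrum()]
#'
#' @param path input file (header line required).
#' @export
read_spectrum <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  if (ncol(tab) < 2) stop("spectrum file must have two columns")
  photon_spectrum(tab[[1]], tab[[2]])
}

#' Filtered beamline spectrum with the standard source settings
#'
#' Convenience wrapper: 2.4 GeV / 1.45 T / 160 mA dipole spectrum filtered
#' by 2.0 mm Be + 3.5 mm Al.
#'
#' @param ring [ring_parameters()].
#' @param filters filter stack, defaults to [default_filters()].
#' @param energy_kev energy grid.
#' @export
beamline_spectrum <- function(ring = ring_parameters(),
                              filters = default_filters(),
                              energy_kev = default_energy_grid()) {
  apply_filters(bending_magnet_spectrum(ring, energy_kev), filters)
}
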