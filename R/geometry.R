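#' @title Multi-slit collimator and beamline geometry
#' @description Ideal periodic tungsten multi-slit collimator (MSC) modelled
#'   in the beamline frame (origin at the source, z along the nominal beam,
#'   x horizontal, y vertical). Rays from the divergent source are traced
#'   through the lamella comb to obtain tungsten path lengths, per-slit
#'   transmission profiles and divergence-induced beam narrowing at the
#'   sample plane.
#' @name beam_geometry
NULL

#' Multi-slit collimator specification
#'
#' @param slit_width_um open slit width, micrometres.
#' @param pitch_um centre-to-centre slit distance, micrometres.
#' @param depth_mm lamella depth along the beam, mm.
#' @param n_slits number of slits in use.
#' @param horizontal_acceptance_mm horizontal aperture, mm.
#' @param vertical_acceptance_mm vertical aperture, mm.
#' @param material lamella material.
#' @export
collimator_spec <- function(slit_width_um = 50, pitch_um = 400,
                            depth_mm = 8, n_slits = 20,
                            horizontal_acceptance_mm = 30,
                            vertical_acceptance_mm = 5,
                            material = "tungsten") {
  stopifnot(slit_width_um > 0, slit_width_um < pitch_um, depth_mm > 0,
            n_slits >= 1)
  if (n_slits * pitch_um / 1000 > horizontal_acceptance_mm + pitch_um / 1000) {
    stop("slit array exceeds the horizontal acceptance")
  }
  structure(list(slit_width_um = slit_width_um, pitch_um = pitch_um,
                 depth_mm = depth_mm, n_slits = n_slits,
                 horizontal_acceptance_mm = horizontal_acceptance_mm,
                 vertical_acceptance_mm = vertical_acceptance_mm,
                 material = material),
            class = "collimator_spec")
}

#' Beamline layout
#'
#' @param source_to_msc_m source to MSC entrance distance, m.
#' @param msc_to_sample_m MSC to sample stage distance, m.
#' @param horizontal_divergence_mrad horizontal beam divergence (FWHM of the
#'   Gaussian angular profile), mrad.
#' @param vertical_divergence_mrad vertical beam divergence (FWHM), mrad.
#' @param vertical_fwhm_at_sample_mm measured vertical Gaussian beam FWHM at
#'   the sample plane, mm.
#' @param source_sigma_x_mm horizontal RMS source size, mm.
#' @param projected_vertical_slit_opening_mm informational: vertical slit
#'   opening projected on the downstream imager, mm.
#' @export
beamline_layout <- function(source_to_msc_m = 15.5, msc_to_sample_m = 0.30,
                            horizontal_divergence_mrad = 7,
                            vertical_divergence_mrad = 0.175,
                            vertical_fwhm_at_sample_mm = 1.5,
                            source_sigma_x_mm = 0.1,
                            projected_vertical_slit_opening_mm = 3.265) {
  stopifnot(source_to_msc_m > 0, msc_to_sample_m > 0,
            horizontal_divergence_mrad > 0, vertical_divergence_mrad > 0)
  structure(list(source_to_msc_m = source_to_msc_m,
                 msc_to_sample_m = msc_to_sample_m,
                 horizontal_divergence_mrad = horizontal_divergence_mrad,
                 vertical_divergence_mrad = vertical_divergence_mrad,
                 vertical_fwhm_at_sample_mm = vertical_fwhm_at_sample_mm,
                 source_sigma_x_mm = source_sigma_x_mm,
                 projected_vertical_slit_opening_mm =
                   projected_vertical_slit_opening_mm),
            class = "beamline_layout")
}

#' Geometric magnification from MSC plane to sample plane
#' @param layout a [beamline_layout()].
#' @export
magnification <- function(layout) {
  (layout$source_to_msc_m + layout$msc_to_sample_m) / layout$source_to_msc_m
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' A forward-going ray in the beamline frame
#'
#' @param origin numeric length-3, mm (x horizontal, y vertical, z along
#'   beam, origin at the source).
#' @param direction numeric length-3; normalized internally; must have a
#'   positive z component.
#' @export
ray <- function(origin, direction) {
  stopifnot(length(origin) == 3, length(direction) == 3)
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("zero direction")
  direction <- direction / nrm
  if (direction[3] <= 0) stop("ray must be forward-going (positive z)")
  structure(list(origin = as.numeric(origin),
                 direction = as.numeric(direction)), class = "ray")
}

#' Slit centre positions at the MSC plane
#' @param msc a [collimator_spec()].
#' @return centre x positions in mm, symmetric about the beam axis.
#' @export
slit_centres <- function(msc) {
  (seq_len(msc$n_slits) - (msc$n_slits + 1) / 2) * msc$pitch_um / 1000
}

# cumulative open (slit) length of (-inf, x], mm; vectorized over x
open_measure <- function(x, msc) {
  ctr <- slit_centres(msc)
  w <- msc$slit_width_um / 2000  # half width in mm
  m <- outer(x, ctr - w, `-`)
  rowSums(pmin(pmax(m, 0), 2 * w))
}

# tungsten path for rays crossing the MSC: x_in at entrance plane, slope
# tan(theta_x) per mm of depth; returns path in mm (vectorized)
tungsten_paths <- function(x_in, slope_x, msc) {
  d <- msc$depth_mm
  x_out <- x_in + slope_x * d
  dx <- x_out - x_in
  geom <- d * sqrt(1 + slope_x^2)   # full traversal length
  open_frac <- ifelse(
    abs(dx) > 1e-12,
    (open_measure(x_out, msc) - open_measure(x_in, msc)) / dx,
    as.numeric(open_measure(x_in + 1e-9, msc) -
                 open_measure(x_in - 1e-9, msc) > 1e-12))
  pmax(geom * (1 - pmin(pmax(open_frac, 0), 1)), 0)
}

#' Tungsten path length of a ray through the MSC
#'
#' Total length of the ray inside lamella material across the collimator
#' depth, from the closed-form crossing of the periodic comb. The MSC
#' entrance plane sits at `z = source_to_msc`.
#'
#' @param r a [ray()].
#' @param msc a [collimator_spec()].
#' @param layout a [beamline_layout()] fixing the MSC entrance plane.
#' @return path length in mm; `NA` (flagged miss) if the ray falls outside
#'   the MSC acceptance.
#' @export
tungsten_path_length <- function(r, msc, layout = beamline_layout()) {
  stopifnot(inherits(r, "ray"), inherits(msc, "collimator_spec"))
  z_msc <- layout$source_to_msc_m * 1000
  t <- (z_msc - r$origin[3]) / r$direction[3]
  if (t < 0) stop("ray starts downstream of the MSC")
  x_in <- r$origin[1] + t * r$direction[1]
  y_in <- r$origin[2] + t * r$direction[2]
  if (abs(x_in) > msc$horizontal_acceptance_mm / 2 ||
      abs(y_in) > msc$vertical_acceptance_mm / 2) {
    return(NA_real_)  # outside acceptance
  }
  slope <- r$direction[1] / r$direction[3]
  tungsten_paths(x_in, slope, msc)
}

#' Transmission of a ray through the MSC at a given energy
#'
#' @inheritParams tungsten_path_length
#' @param energy_kev photon energy in keV.
#' @return transmitted fraction in `[0, 1]`; `NA` for a flagged miss.
#' @export
ray_transmission <- function(r, energy_kev, msc,
                             layout = beamline_layout()) {
  path_mm <- tungsten_path_length(r, msc, layout)
  if (is.na(path_mm)) return(NA_real_)
  exp(-linear_attenuation(msc$material, energy_kev) * path_mm / 10)
}

#' Effective (FWHM) width of one slit's beam at the sample plane
#'
#' Ray-traces the transmission profile of a single slit for the point-like
#' divergent source and reports the FWHM at the sample plane. Off-axis
#' slits narrow because oblique rays walk laterally across the lamella
#' depth by `depth * x / source_to_msc`.
#'
#' @param slit_centre_x_mm slit centre at the MSC plane, mm.
#' @param msc a [collimator_spec()].
#' @param layout a [beamline_layout()].
#' @param energy_kev reference energy for tungsten opacity.
#' @param projected if `TRUE` report the width at the sample plane
#'   (includes the geometric magnification); if `FALSE` de-magnify to
#'   MSC-plane (nominal) units.
#' @return FWHM in micrometres.
#' @export
effective_slit_width <- function(slit_centre_x_mm, msc = collimator_spec(),
                                 layout = beamline_layout(),
                                 energy_kev = 30, projected = TRUE) {
  if (abs(slit_centre_x_mm) > msc$horizontal_acceptance_mm / 2) {
    stop("slit outside the horizontal acceptance")
  }
  # single-slit comb centred at slit_centre_x_mm
  one <- collimator_spec(slit_width_um = msc$slit_width_um,
                         pitch_um = msc$pitch_um, depth_mm = msc$depth_mm,
                         n_slits = 1,
                         horizontal_acceptance_mm =
                           msc$horizontal_acceptance_mm,
                         vertical_acceptance_mm =
                           msc$vertical_acceptance_mm,
                         material = msc$material)
  L <- layout$source_to_msc_m * 1000
  mag <- magnification(layout)
  half <- msc$slit_width_um / 1000  # scan +-1 slit width around the centre
  xs <- seq(slit_centre_x_mm - half, slit_centre_x_mm + half,
            by = 5e-5)  # 0.05 um steps at the MSC plane
  # point source at the origin: the ray through MSC-entrance x has slope
  # x/L; work in a frame where the single slit of `one` is centred at 0
  paths <- tungsten_paths(xs - slit_centre_x_mm, xs / L, one)
  trans <- exp(-linear_attenuation(msc$material, energy_kev) * paths / 10)
  half_max <- max(trans) / 2
  above <- trans >= half_max
  if (!any(above)) stop("no transmission through slit")
  # FWHM by linear interpolation at the half-max crossings
  idx <- range(which(above))
  x_lo <- if (idx[1] > 1) {
    stats::approx(trans[(idx[1] - 1):idx[1]], xs[(idx[1] - 1):idx[1]],
                  half_max)$y
  } else xs[1]
  x_hi <- if (idx[2] < length(xs)) {
    stats::approx(trans[idx[2]:(idx[2] + 1)], xs[idx[2]:(idx[2] + 1)],
                  half_max)$y
  } else xs[length(xs)]
  fwhm_msc_um <- (x_hi - x_lo) * 1000
  if (projected) fwhm_msc_um * mag else fwhm_msc_um
}

#' Horizontal extent of the central microbeam array
#'
#' @param n_central number of central microbeams used.
#' @param msc a [collimator_spec()].
#' @return extent `n_central * pitch` in mm (nominal, at the MSC plane).
#' @export
array_extent <- function(n_central, msc = collimator_spec()) {
  stopifnot(n_central >= 1)
  if (n_central > msc$n_slits) stop("n_central exceeds available slits")
  n_central * msc$pitch_um / 1000
}
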