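#' @title Material attenuation data
#' @description Packaged mass-attenuation tables (5--150 keV) for the
#'   materials used throughout the beamline model: beryllium and aluminium
#'   (filters), tungsten (collimator lamellae), water (phantom) and air.
#'   Tables carry the total coefficient (with coherent) plus the
#'   photoelectric, incoherent and coherent partials, which sum to the total
#'   by construction. Lookups interpolate log-log between nodes.
#' @name materials
NULL

.materials_env <- new.env(parent = emptyenv())

supported_materials <- function() {
  c("beryllium", "aluminium", "tungsten", "water", "air")
}

materials_path <- function(file) {
  system.file("extdata", "materials", file, package = "mbdosim",
              mustWork = TRUE)
}

#' Load the packaged attenuation table for a material
#'
#' @param material one of `supported_materials()`.
#' @return data.frame with columns `energy_keV`, `total`, `photoelectric`,
#'   `incoherent`, `coherent` (all coefficients in cm^2/g).
#' @export
material_table <- function(material) {
  material <- match.arg(material, supported_materials())
  key <- paste0("tab_", material)
  if (is.null(.materials_env[[key]])) {
    tab <- utils::read.table(materials_path(paste0(material, ".tsv")),
                             header = TRUE, sep = "\t")
    stopifnot(!is.unsorted(tab$energy_keV), all(tab$total > 0))
    .materials_env[[key]] <- tab
  }
  .materials_env[[key]]
}

#' Density registry for the supported materials
#'
#' @param material material identifier.
#' @return density in g/cm^3.
#' @export
material_density <- function(material) {
  material <- match.arg(material, supported_materials())
  if (is.null(.materials_env$densities)) {
    .materials_env$densities <- utils::read.table(
      materials_path("densities.tsv"), header = TRUE, sep = "\t")
  }
  d <- .materials_env$densities
  d$density_g_cm3[match(material, d$material)]
}

#' Mass attenuation coefficient by log-log interpolation
#'
#' @param material material identifier.
#' @param energy_kev photon energies in keV (vectorized); must lie within
#'   the tabulated range.
#' @param kind which coefficient: `"total"` (with coherent),
#'   `"photoelectric"`, `"incoherent"` or `"coherent"`.
#' @return mass attenuation coefficient(s) in cm^2/g.
#' @export
attenuation_coefficient <- function(material, energy_kev,
                                    kind = c("total", "photoelectric",
                                             "incoherent", "coherent")) {
  kind <- match.arg(kind)
  tab <- material_table(material)
  if (any(!is.finite(energy_kev)) || any(energy_kev < min(tab$energy_keV)) ||
      any(energy_kev > max(tab$energy_keV))) {
    stop(sprintf("energy out of tabulated range [%g, %g] keV for %s",
                 min(tab$energy_keV), max(tab$energy_keV), material))
  }
  # duplicated edge nodes (tungsten L/K edges) are carried as pairs a
  # fraction of an eV apart; approx() with ties = "ordered" keeps the jump
  exp(stats::approx(log(tab$energy_keV), log(tab[[kind]]), log(energy_kev),
                    ties = "ordered")$y)
}

# linear attenuation coefficient, 1/cm
linear_attenuation <- function(material, energy_kev, kind = "total") {
  attenuation_coefficient(material, energy_kev, kind) *
    material_density(material)
}

#' Construct a beam filter element
#'
#' @param material material identifier (must be in the packaged tables).
#' @param thickness_mm thickness in mm, >= 0.
#' @export
filter_element <- function(material, thickness_mm) {
  material <- match.arg(material, supported_materials())
  if (!is.numeric(thickness_mm) || length(thickness_mm) != 1 ||
      thickness_mm < 0) {
    stop("thickness_mm must be a single non-negative number")
  }
  structure(list(material = material, thickness_mm = thickness_mm),
            class = "filter_element")
}

#' Transmission of a filter stack
#'
#' Product over elements of `exp(-(mu/rho) * rho * t)`; order of the stack
#' is irrelevant.
#'
#' @param filters list of [filter_element()] objects (may be empty).
#' @param energy_kev photon energies in keV (vectorized).
#' @return transmitted fraction(s) in `[0, 1]`.
#' @export
filter_transmission <- function(filters, energy_kev) {
  if (inherits(filters, "filter_element")) filters <- list(filters)
  trans <- rep(1, length(energy_kev))
  for (f in filters) {
    stopifnot(inherits(f, "filter_element"))
    mu <- linear_attenuation(f$material, energy_kev)
    trans <- trans * exp(-mu * f$thickness_mm / 10)
  }
  trans
}

#' Default beamline filtration: 2.0 mm beryllium + 3.5 mm aluminium
#' @export
default_filters <- function() {
  list(filter_element("beryllium", 2.0), filter_element("aluminium", 3.5))
}
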