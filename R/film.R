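#' @title Radiochromic film dosimetry
#' @description Net optical density computation, monotone calibration
#'   fitting, dose-map conversion and peak-region analysis for Gafchromic
#'   EBT3 / HD-V2 style films read out as single-channel (grayscale)
#'   microphotographs.
#' @name film_dosimetry
NULL

#' Film type registry
#'
#' EBT3: dynamic dose range 0.1--20 Gy, spatial resolution ~25 um.
#' HD-V2: 10--1000 Gy, ~5 um.
#'
#' @param type `"EBT3"` or `"HD-V2"`.
#' @return list with `dose_range_gy` and `resolution_um` (treated as the
#'   FWHM of the film + readout point-spread function).
#' @export
film_type <- function(type = c("EBT3", "HD-V2")) {
  type <- match.arg(type)
  switch(type,
         "EBT3" = list(name = "EBT3", dose_range_gy = c(0.1, 20),
                       resolution_um = 25),
         "HD-V2" = list(name = "HD-V2", dose_range_gy = c(10, 1000),
                        resolution_um = 5))
}

#' Film image container
#'
#' @param data numeric matrix of pixel intensities (16-bit scale,
#'   0..65535).
#' @param pixel_size_um pixel pitch, micrometres.
#' @param type film type name, `"EBT3"` or `"HD-V2"`.
#' @param reference_intensity unexposed-film intensity on the same scale.
#' @export
film_image <- function(data, pixel_size_um, type = "EBT3",
                       reference_intensity = 40000) {
  data <- as.matrix(data)
  stopifnot(pixel_size_um > 0, reference_intensity > 0)
  if (any(data < 0) || any(data > 65535)) {
    stop("intensities must lie within the 16-bit range")
  }
  structure(list(data = data, pixel_size_um = pixel_size_um,
                 film = film_type(type),
                 reference_intensity = reference_intensity),
            class = "film_image")
}

#' Net optical density of a film image
#'
#' `netOD = log10(reference / intensity)`, clipped at zero; zero-intensity
#' (saturated) pixels are flagged `NA`.
#'
#' @param image a [film_image()] or a numeric matrix.
#' @param reference unexposed reference intensity (taken from the image
#'   object if missing).
#' @return matrix of net optical densities with a `saturated` attribute.
#' @export
net_od <- function(image, reference = NULL) {
  if (inherits(image, "film_image")) {
    if (is.null(reference)) reference <- image$reference_intensity
    image <- image$data
  }
  if (is.null(reference) || reference <= 0) {
    stop("a positive reference intensity is required")
  }
  sat <- image <= 0
  od <- matrix(NA_real_, nrow(image), ncol(image))
  od[!sat] <- pmax(log10(reference / image[!sat]), 0)
  attr(od, "saturated") <- sat
  od
}

#' Fit a monotone netOD-to-dose calibration curve
#'
#' Least-squares fit of the rational monotone model
#' `D = a * netOD + b * netOD^n` with fixed exponent `n` (linear in `a`,
#' `b`). The fitted curve must be strictly increasing over the data range.
#'
#' @param net_ods calibration net optical densities (>= 3 points).
#' @param doses_gy corresponding doses, Gy.
#' @param exponent fixed exponent `n` of the nonlinear term.
#' @param film type name used to record the valid dose range.
#' @return a `calibration_curve`: coefficients, exponent, valid ranges and
#'   fit residuals.
#' @export
fit_calibration <- function(net_ods, doses_gy, exponent = 2.5,
                            film = "EBT3") {
  stopifnot(length(net_ods) == length(doses_gy))
  if (length(net_ods) < 3) stop("at least 3 calibration points required")
  o <- order(net_ods)
  net_ods <- net_ods[o]
  doses_gy <- doses_gy[o]
  if (is.unsorted(doses_gy, strictly = TRUE)) {
    stop("calibration data must be monotone (dose increasing with netOD)")
  }
  fit <- stats::lm(doses_gy ~ 0 + net_ods + I(net_ods^exponent))
  coefs <- stats::coef(fit)
  a <- unname(coefs[1])
  b <- unname(coefs[2])
  # monotonicity of a*x + b*x^n over the fitted range
  xs <- seq(max(min(net_ods), 1e-6), max(net_ods), length.out = 200)
  deriv <- a + b * exponent * xs^(exponent - 1)
  if (any(deriv <= 0)) stop("fitted calibration is not strictly monotone")
  structure(list(a = a, b = b, exponent = exponent,
                 od_range = range(net_ods), dose_range_gy = range(doses_gy),
                 film = film, residuals = unname(stats::residuals(fit))),
            class = "calibration_curve")
}

#' Evaluate a calibration curve: netOD to dose
#' @param curve a `calibration_curve`.
#' @param net_od net optical densities.
#' @return doses in Gy.
#' @export
calibration_dose <- function(curve, net_od) {
  stopifnot(inherits(curve, "calibration_curve"))
  curve$a * net_od + curve$b * net_od^curve$exponent
}

#' Invert a calibration curve: dose to netOD
#' @param curve a `calibration_curve`.
#' @param dose_gy doses in Gy (non-negative).
#' @return net optical densities (bisection on the monotone model).
#' @export
calibration_od <- function(curve, dose_gy) {
  stopifnot(inherits(curve, "calibration_curve"), all(dose_gy >= 0))
  hi <- max(curve$od_range[2], 1)
  dmax <- max(dose_gy, 0)
  while (calibration_dose(curve, hi) < dmax) hi <- hi * 2
  # monotone inverse by dense interpolation + one Newton refinement
  ods <- seq(0, hi, length.out = 4096)
  od <- stats::approx(calibration_dose(curve, ods), ods, dose_gy,
                      rule = 2)$y
  deriv <- curve$a + curve$b * curve$exponent *
    pmax(od, 1e-12)^(curve$exponent - 1)
  pmax(od - (calibration_dose(curve, od) - dose_gy) / deriv, 0)
}

#' A nominal synthetic calibration curve for a film type
#'
#' Convenience constructor used by the synthetic-film generator: a
#' monotone curve whose netOD span [0, ~0.8] covers the film's dynamic
#' dose range. Synthetic stand-in; real calibrations come from
#' [fit_calibration()] on measured points.
#'
#' @param type `"EBT3"` or `"HD-V2"`.
#' @export
default_calibration <- function(type = c("EBT3", "HD-V2")) {
  type <- match.arg(type)
  ft <- film_type(type)
  ods <- seq(0.05, 0.8, length.out = 8)
  pars <- if (type == "EBT3") c(a = 8, b = 30) else c(a = 300, b = 1500)
  doses <- pars["a"] * ods + pars["b"] * ods^2.5
  fit_calibration(ods, doses, exponent = 2.5, film = type)
}

#' Convert a film image to a dose map
#'
#' Pixelwise netOD-to-dose mapping; pixels outside the film's dynamic dose
#' range are flagged `NA` rather than extrapolated.
#'
#' @param image a [film_image()].
#' @param curve a `calibration_curve`.
#' @return matrix of doses (Gy) with an `out_of_range` attribute.
#' @export
to_dose_map <- function(image, curve) {
  stopifnot(inherits(image, "film_image"),
            inherits(curve, "calibration_curve"))
  if (!identical(curve$film, image$film$name)) {
    warning(sprintf("calibration fitted for %s applied to a %s image",
                    curve$film, image$film$name))
  }
  od <- net_od(image)
  dose <- calibration_dose(curve, od)
  rng <- image$film$dose_range_gy
  oor <- !is.na(dose) & (dose < rng[1] | dose > rng[2])
  dose[oor] <- NA_real_
  attr(dose, "out_of_range") <- oor
  attr(dose, "pixel_size_um") <- image$pixel_size_um
  dose
}

#' Peak dose from a film dose map
#'
#' Mean dose over `region_x_um x region_y_um` regions centred on the
#' microbeam peaks, pooled over regions (and over repeated vertical
#' placements emulating several fields of view) with a standard error.
#'
#' @param dose_map matrix from [to_dose_map()] (needs the
#'   `pixel_size_um` attribute, or supply `pixel_size_um`).
#' @param centres_mm horizontal microbeam centre positions, mm (x = 0 at
#'   the map centre).
#' @param region_x_um,region_y_um analysis region size (the 40 x 100 um
#'   peak-region convention).
#' @param n_regions number of vertically stacked regions per beam (>= 2).
#' @param pixel_size_um pixel pitch override.
#' @return list with pooled `dose`, `stderr`, and per-region values.
#' @export
film_peak_dose <- function(dose_map, centres_mm, region_x_um = 40,
                           region_y_um = 100, n_regions = 3,
                           pixel_size_um = NULL) {
  if (is.null(pixel_size_um)) {
    pixel_size_um <- attr(dose_map, "pixel_size_um")
  }
  if (is.null(pixel_size_um)) stop("pixel size unknown")
  if (n_regions < 2) stop("at least two regions per beam are required")
  nx <- nrow(dose_map)
  ny <- ncol(dose_map)
  cx <- (seq_len(nx) - (nx + 1) / 2) * pixel_size_um / 1000
  hw <- region_x_um / 2 / 1000
  hh_px <- max(1, round(region_y_um / pixel_size_um))
  # vertically stacked regions around the map centre
  y0 <- round(ny / 2)
  starts <- y0 + (seq_len(n_regions) - (n_regions + 1) / 2) * hh_px -
    hh_px / 2
  vals <- c()
  for (c0 in centres_mm) {
    sel_x <- which(abs(cx - c0) <= hw)
    if (length(sel_x) == 0) stop("peak region outside the image")
    for (s in starts) {
      rows <- max(1, round(s)):min(ny, round(s) + hh_px - 1)
      if (length(rows) == 0) stop("peak region outside the image")
      vals <- c(vals, mean(dose_map[sel_x, rows], na.rm = TRUE))
    }
  }
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0) stop("no usable peak regions")
  list(dose = mean(vals), stderr = stats::sd(vals) / sqrt(length(vals)),
       per_region = vals)
}

#' Write a film image as 16-bit grayscale TIFF with a JSON sidecar
#' @param image a [film_image()].
#' @param path output TIFF path; sidecar written to `<path>.json`.
#' @export
write_film <- function(image, path) {
  stopifnot(inherits(image, "film_image"))
  tiff::writeTIFF(t(image$data) / 65535, path, bits.per.sample = 16L)
  jsonlite::write_json(list(pixel_size_um = image$pixel_size_um,
                            film_type = image$film$name,
                            reference_intensity = image$reference_intensity),
                       paste0(path, ".json"), auto_unbox = TRUE)
}

#' Read a film image written by [write_film()]
#' @param path TIFF path (JSON sidecar `<path>.json` expected).
#' @export
read_film <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"),
                              simplifyVector = TRUE)
  img <- tiff::readTIFF(path)
  film_image(round(t(img) * 65535), side$pixel_size_um, side$film_type,
             side$reference_intensity)
}

#' Read a calibration table (netOD, dose_Gy) from delimited text
#' @param path file with header columns `netOD` and `dose_Gy`.
#' @export
read_calibration_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("netOD", "dose_Gy") %in% names(tab))) {
    stop("calibration table needs columns netOD and dose_Gy")
  }
  tab
}
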