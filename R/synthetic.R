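#' @title Synthetic-data generators
#' @description Seeded generators for every input the analysis chain
#'   consumes: microbeam-array film images with film-specific blur, noise
#'   and quantization, and replicate cell-count tables with multiplicative
#'   (lognormal) noise. Every generator returns its ground truth so the
#'   downstream stages can be tested by recovery.
#' @name synthetic_data
NULL

#' Specification of a synthetic microbeam film exposure
#'
#' @param beam_width_um microbeam width.
#' @param pitch_um centre-to-centre distance.
#' @param n_beams number of microbeams.
#' @param peak_dose_gy dose in the beam paths.
#' @param valley_dose_gy dose between the beams.
#' @param envelope `"flat"` (scanned field) or `"gaussian"` (static
#'   vertical envelope).
#' @param envelope_fwhm_mm vertical FWHM when `envelope = "gaussian"`.
#' @param film_type `"EBT3"` or `"HD-V2"`.
#' @param pixel_size_um readout pixel pitch.
#' @param psf_sigma_um Gaussian point-spread sigma; defaults to the film
#'   resolution (FWHM) converted to sigma.
#' @param noise_cv multiplicative intensity noise (coefficient of
#'   variation).
#' @param noise_additive additive intensity noise (16-bit counts, sd).
#' @param width_mm,height_mm film patch size.
#' @param seed RNG seed.
#' @export
synth_film_spec <- function(beam_width_um = 50, pitch_um = 400,
                            n_beams = 20, peak_dose_gy = 65,
                            valley_dose_gy = 0.53,
                            envelope = c("flat", "gaussian"),
                            envelope_fwhm_mm = 1.5, film_type = "EBT3",
                            pixel_size_um = NULL, psf_sigma_um = NULL,
                            noise_cv = 0.02, noise_additive = 100,
                            width_mm = NULL, height_mm = 3, seed = 1L) {
  envelope <- match.arg(envelope)
  stopifnot(peak_dose_gy > valley_dose_gy, valley_dose_gy >= 0)
  ft <- film_type(film_type)
  if (is.null(pixel_size_um)) pixel_size_um <- ft$resolution_um / 5
  if (is.null(psf_sigma_um)) psf_sigma_um <- fwhm_to_sigma(ft$resolution_um)
  if (is.null(width_mm)) width_mm <- (n_beams + 1) * pitch_um / 1000
  structure(list(beam_width_um = beam_width_um, pitch_um = pitch_um,
                 n_beams = n_beams, peak_dose_gy = peak_dose_gy,
                 valley_dose_gy = valley_dose_gy, envelope = envelope,
                 envelope_fwhm_mm = envelope_fwhm_mm,
                 film_type = ft$name, pixel_size_um = pixel_size_um,
                 psf_sigma_um = psf_sigma_um, noise_cv = noise_cv,
                 noise_additive = noise_additive, width_mm = width_mm,
                 height_mm = height_mm, seed = as.integer(seed)),
            class = "synth_film_spec")
}

# separable Gaussian blur of a matrix, sigma in pixels
gaussian_blur <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  half <- max(1, ceiling(3 * sigma_px))
  k <- stats::dnorm(-half:half, sd = sigma_px)
  k <- k / sum(k)
  pad_conv <- function(v) {
    n <- length(v)
    vp <- c(rep(v[1], half), v, rep(v[n], half))
    stats::filter(vp, k, sides = 2)[(half + 1):(half + n)]
  }
  m <- apply(m, 2, pad_conv)
  t(apply(t(m), 2, pad_conv))
}

#' Generate a synthetic microbeam film image with ground truth
#'
#' Builds the nominal dose pattern, maps it to film intensity through the
#' inverse of the film's nominal calibration, applies the film + readout
#' point-spread function, multiplicative and additive intensity noise, and
#' 16-bit quantization.
#'
#' @param spec a [synth_film_spec()].
#' @return list with `image` (a [film_image()]), `truth` (noise-free dose
#'   matrix, Gy), `truth_pvdr`, and the calibration `curve` used.
#' @export
synth_film <- function(spec) {
  stopifnot(inherits(spec, "synth_film_spec"))
  set.seed(spec$seed)
  px_mm <- spec$pixel_size_um / 1000
  nx <- max(2, round(spec$width_mm / px_mm))
  ny <- max(2, round(spec$height_mm / px_mm))
  x <- (seq_len(nx) - (nx + 1) / 2) * px_mm
  y <- (seq_len(ny) - (ny + 1) / 2) * px_mm
  ctr <- (seq_len(spec$n_beams) - (spec$n_beams + 1) / 2) *
    spec$pitch_um / 1000
  in_beam <- rep(FALSE, nx)
  for (c0 in ctr) {
    in_beam <- in_beam | abs(x - c0) <= spec$beam_width_um / 2000
  }
  profile <- ifelse(in_beam, spec$peak_dose_gy, spec$valley_dose_gy)
  env <- if (spec$envelope == "gaussian") {
    exp(-y^2 / (2 * fwhm_to_sigma(spec$envelope_fwhm_mm)^2))
  } else {
    rep(1, ny)
  }
  truth <- outer(profile, env)
  rng <- film_type(spec$film_type)$dose_range_gy
  if (all(truth < rng[1]) || all(truth > rng[2])) {
    warning("dose pattern lies wholly outside the film dynamic range")
  }
  curve <- default_calibration(spec$film_type)
  ref <- 40000
  od <- matrix(calibration_od(curve, pmax(as.vector(truth), 0)), nx, ny)
  intensity <- ref * 10^(-od)
  intensity <- gaussian_blur(intensity,
                             spec$psf_sigma_um / spec$pixel_size_um)
  noisy <- intensity * exp(stats::rnorm(nx * ny, 0, spec$noise_cv)) +
    stats::rnorm(nx * ny, 0, spec$noise_additive)
  quant <- matrix(pmin(pmax(round(noisy), 0), 65535), nx, ny)
  img <- film_image(quant, spec$pixel_size_um, spec$film_type, ref)
  list(image = img, truth = truth,
       truth_pvdr = spec$peak_dose_gy / spec$valley_dose_gy,
       curve = curve)
}

#' Specification of a synthetic cell-count experiment
#'
#' Emulates triplicate counts of irradiated (MBI) and control melanoma
#' cultures at 24 h and 72 h, with multiplicative lognormal replicate
#' noise.
#'
#' @param control_means named vector of control mean counts per timepoint
#'   (hours as names).
#' @param survival named vector of treated/control survival fractions per
#'   timepoint.
#' @param replicates replicates per condition and timepoint (>= 2).
#' @param cv lognormal coefficient of variation of replicate counts.
#' @param seed RNG seed.
#' @export
synth_cell_spec <- function(control_means = c(`24` = 20000, `72` = 40000),
                            survival = c(`24` = 0.205, `72` = 0.235),
                            replicates = 3, cv = 0.1, seed = 1L) {
  stopifnot(all(survival >= 0), all(survival <= 1), replicates >= 2,
            all(names(survival) %in% names(control_means)))
  structure(list(control_means = control_means, survival = survival,
                 replicates = replicates, cv = cv,
                 seed = as.integer(seed)),
            class = "synth_cell_spec")
}

#' Generate a synthetic cell-count table
#'
#' Lognormal replicate counts around the control mean and around
#' control x survival for the irradiated condition, seeded.
#'
#' @param spec a [synth_cell_spec()].
#' @return data.frame with columns `condition` (`control` / `MBI`),
#'   `timepoint_h`, `replicate`, `count`.
#' @export
synth_cell_counts <- function(spec) {
  stopifnot(inherits(spec, "synth_cell_spec"))
  set.seed(spec$seed)
  sdlog <- sqrt(log(1 + spec$cv^2))
  rows <- list()
  for (tp in names(spec$survival)) {
    for (cond in c("control", "MBI")) {
      m <- spec$control_means[[tp]] *
        if (cond == "MBI") spec$survival[[tp]] else 1
      meanlog <- log(m) - sdlog^2 / 2
      counts <- stats::rlnorm(spec$replicates, meanlog, sdlog)
      rows[[length(rows) + 1]] <- data.frame(
        condition = cond, timepoint_h = as.numeric(tp),
        replicate = seq_len(spec$replicates), count = counts)
    }
  }
  do.call(rbind, rows)
}
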