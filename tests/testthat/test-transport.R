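# Monte Carlo source, attenuation and in-water interaction physics

test_that("analogue launch geometry matches the configured source", {
  sp <- beamline_spectrum(energy_kev = seq(10, 100, by = 1))
  msc <- collimator_spec()
  layout <- beamline_layout()
  cfg <- small_transport(importance_sampling = FALSE)
  set.seed(5)
  ph <- launch_photons(2e5, sp, msc, layout, cfg)
  # weights all one without importance sampling
  expect_true(all(ph$weight == 1))
  # angular standard deviation matches the divergence within 1%
  sig_th <- mbdosim:::fwhm_to_sigma(7e-3)
  expect_equal(sd(ph$slope_x), sig_th, tolerance = 0.01)
  # near the array centre the slit-hit fraction is the open fraction
  near <- abs(ph$x_msc_mm) < 2
  hit <- mbdosim:::open_measure(ph$x_msc_mm[near] + 1e-9, msc) -
    mbdosim:::open_measure(ph$x_msc_mm[near] - 1e-9, msc) > 1e-12
  p_hat <- mean(hit)
  se <- sqrt(0.125 * 0.875 / sum(near))
  expect_lt(abs(p_hat - 50 / 400), 4 * se + 0.002)
})

test_that("importance sampling restricts positions to slit windows with weight Q", {
  sp <- beamline_spectrum(energy_kev = seq(10, 100, by = 1))
  msc <- collimator_spec()
  cfg <- small_transport(importance_sampling = TRUE, slit_margin_um = 25)
  set.seed(6)
  ph <- launch_photons(1e4, sp, msc, beamline_layout(), cfg)
  expect_true(all(ph$weight > 0 & ph$weight <= 1))
  expect_equal(length(unique(ph$weight)), 1)  # equal-weight scheme
  # every sampled position lies inside a widened slit window
  ctr <- slit_centres(msc)
  h <- (msc$slit_width_um / 2 + cfg$slit_margin_um) / 1000
  in_win <- vapply(ph$x_msc_mm, function(x) any(abs(x - ctr) <= h + 1e-12),
                   logical(1))
  expect_true(all(in_win))
})

test_that("deterministic transmission attenuates tungsten and air correctly", {
  msc <- collimator_spec()
  layout <- beamline_layout()
  cfg <- small_transport()
  mono <- structure(list(x_msc_mm = c(0.2, 0.4), y_mm = c(0, 0),
                         slope_x = c(0, 0), energy_kev = c(30, 30),
                         weight = c(1, 1), q_window = 1, n_launched = 2),
                    class = "photon_bundle")
  out <- transmit_to_phantom(mono, msc, layout, cfg)
  # the lamella-centre photon is terminated far below the weight floor
  expect_equal(length(out$weight), 1)
  # the slit-centre photon loses only ~1.3% to 30 cm of air at 30 keV
  air_t <- exp(-mbdosim:::linear_attenuation("air", 30) * 30)
  expect_equal(out$weight, air_t, tolerance = 1e-10)
  expect_gt(out$weight, 0.95)
  # with air disabled the slit-centre weight is untouched
  cfg0 <- small_transport(air_density_scale = 0)
  out0 <- transmit_to_phantom(mono, msc, layout, cfg0)
  expect_equal(out0$weight[1], 1)
})

test_that("Klein-Nishina limits and sampled energies match quadrature", {
  # Thomson limit
  expect_equal(klein_nishina_sigma(1e-4), 0.6652, tolerance = 1e-3)
  expect_lt(klein_nishina_sigma(100), klein_nishina_sigma(10))
  # mean scattered-photon energy fraction at 30 keV against a quadrature
  # oracle on the differential cross section
  a <- 30 / 510.99895
  dsig <- function(ct) {
    r <- 1 / (1 + a * (1 - ct))
    r^2 * (r + 1 / r - (1 - ct^2))
  }
  num <- integrate(function(ct) dsig(ct) / (1 + a * (1 - ct)), -1, 1,
                   rel.tol = 1e-10)$value
  den <- integrate(dsig, -1, 1, rel.tol = 1e-10)$value
  oracle <- num / den
  set.seed(8)
  ct <- mbdosim:::kn_sample_cos(rep(30, 2e5))
  frac <- 1 / (1 + a * (1 - ct))
  expect_equal(mean(frac), oracle, tolerance = 0.005)
})

test_that("Rayleigh sampling is forward-peaked at these energies", {
  set.seed(9)
  ct30 <- mbdosim:::rayleigh_sample_cos(rep(30, 2e4))
  expect_gt(mean(ct30), 0.5)  # strongly forward
  ct10 <- mbdosim:::rayleigh_sample_cos(rep(10, 2e4))
  expect_gt(mean(ct30), mean(ct10))  # more forward at higher energy
})

test_that("forced interaction deposits energy only inside the slab and conserves it", {
  phantom <- phantom_spec(entrance_layer_mm = 0, exit_layer_mm = 0)
  cfg <- small_transport(coherent = FALSE)
  set.seed(10)
  n <- 5e3
  ph <- structure(list(x_mm = rep(0, n), y_mm = rep(0, n),
                       z_mm = rep(0, n), dx = rep(0, n), dy = rep(0, n),
                       dz = rep(1, n), energy_kev = rep(30, n),
                       weight = rep(1, n), q_window = 1, n_launched = n),
                  class = "photon_bundle")
  res <- interact_in_water(ph, phantom, cfg)
  expect_true(all(res$deposits$z_mm >= 0 &
                    res$deposits$z_mm <= phantom$thickness_mm))
  total_dep <- sum(res$deposits$energy) +
    if (!is.null(res$survivors)) {
      sum(res$survivors$weight * res$survivors$energy_kev)
    } else 0
  # deposited + surviving energy equals the interacting fraction
  p_int <- -expm1(-mbdosim:::linear_attenuation(
    "water", 30, "photoelectric") / 10 -
      mbdosim:::linear_attenuation("water", 30, "incoherent") / 10)
  expect_equal(total_dep / n, p_int * 30, tolerance = 0.02)
  # zero-weight photons deposit nothing
  ph0 <- ph
  ph0$weight <- rep(0, n)
  expect_equal(sum(interact_in_water(ph0, phantom, cfg)$deposits$energy), 0)
})

test_that("static field peaks at slit projections with the expected width", {
  cfg <- small_transport(n = 1.2e5, seed = 31)
  g <- run_static_field(cfg, grid = small_grid())
  # energy conservation: scored never exceeds launched
  expect_lte(g$meta$scored_kev, g$meta$launched_kev)
  prof <- horizontal_profile(g, vertical_window_mm = 0.5)
  centres <- detect_peaks(prof, 400)
  mag <- magnification(beamline_layout())
  expect_equal(mean(diff(centres)), 0.4 * mag, tolerance = 0.01)
  # FWHM of the central beam ~ effective slit width (projected);
  # apex from the beam-top average, crossings by linear interpolation
  i <- which.min(abs(centres))
  sel <- abs(prof$positions_mm - centres[i]) < 0.1
  d <- prof$dose[sel]; x <- prof$positions_mm[sel]
  apex <- mean(d[abs(x - centres[i]) <= 0.010])
  above <- which(d >= apex / 2)
  lo <- min(above); hi <- max(above)
  x_lo <- if (lo > 1) approx(d[c(lo - 1, lo)], x[c(lo - 1, lo)],
                             apex / 2)$y else x[1]
  x_hi <- if (hi < length(x)) approx(d[c(hi, hi + 1)], x[c(hi, hi + 1)],
                                     apex / 2)$y else x[length(x)]
  fwhm <- (x_hi - x_lo) * 1000
  expect_equal(fwhm, 50 * mag, tolerance = 0.15)
  # left-right mirror symmetry of the peak doses within statistics
  pk <- peak_dose(prof, centres)$per_beam
  left <- pk$dose[order(pk$centre_mm)]
  right <- rev(left)
  expect_equal(left, right, tolerance = 0.1)
})

test_that("uncertainty scales as one over root N", {
  g1 <- run_static_field(small_transport(n = 4e4, seed = 13),
                         grid = small_grid())
  g2 <- run_static_field(small_transport(n = 16e4, seed = 13),
                         grid = small_grid())
  # well-sampled (peak) voxels only: sparse halo voxels carry too few
  # events per batch for a stable per-voxel variance estimate
  sel <- g1$values > 0.2 * max(g1$values) &
    g2$values > 0.2 * max(g2$values)
  r <- median(g1$stderr[sel] / g1$values[sel]) /
    median(g2$stderr[sel] / g2$values[sel])
  expect_equal(r, 2, tolerance = 0.25)
})

test_that("the no-scatter opaque-collimator limit has exactly zero valley", {
  cfg <- small_transport(n = 4e4, seed = 17, max_generations = 1,
                         electron_blur_sigma_um = 0, coherent = FALSE)
  g <- run_static_field(cfg, grid = small_grid())
  prof <- horizontal_profile(g, vertical_window_mm = 1)
  centres <- detect_peaks(prof, 400)
  vl <- valley_dose(prof, centres)
  expect_identical(vl$dose, 0)
  res <- pvdr(peak_dose(prof, centres), vl)
  expect_true(res$lower_bound_only)
  expect_identical(res$pvdr, Inf)
})

test_that("importance sampling is unbiased for the peak dose", {
  sp <- beamline_spectrum()
  msc <- collimator_spec(n_slits = 4)
  on <- run_static_field(small_transport(n = 6e4, seed = 19),
                         spectrum = sp, msc = msc, grid = small_grid())
  off <- run_static_field(
    small_transport(n = 6e6, seed = 23, importance_sampling = FALSE),
    spectrum = sp, msc = msc, grid = small_grid())
  p_on <- peak_dose(horizontal_profile(on, 1),
                    detect_peaks(horizontal_profile(on, 1), 400))
  p_off <- peak_dose(horizontal_profile(off, 1),
                     detect_peaks(horizontal_profile(off, 1), 400))
  # per-effective-history peak dose agrees within combined uncertainty
  # (batch stderr at this size is itself noisy, hence the floor term)
  tol <- 3 * sqrt(p_on$stderr^2 + p_off$stderr^2) + 0.08 * p_on$dose
  expect_lt(abs(p_on$dose - p_off$dose), tol)
})

test_that("runs are reproducible for a fixed seed", {
  g1 <- run_static_field(small_transport(n = 2e4, seed = 29),
                         grid = small_grid())
  g2 <- run_static_field(small_transport(n = 2e4, seed = 29),
                         grid = small_grid())
  expect_identical(g1$values, g2$values)
  g3 <- run_static_field(small_transport(n = 2e4, seed = 30),
                         grid = small_grid())
  expect_false(identical(g1$values, g3$values))
})

test_that("dose grids serialize and reload losslessly", {
  g <- run_static_field(small_transport(n = 2e4, seed = 3),
                        grid = grid_spec(x_pitch_um = 20, y_pitch_um = 400,
                                         x_half_mm = 2.2, y_half_mm = 8))
  path <- tempfile(fileext = ".tsv")
  write_dose_grid(g, path)
  back <- read_dose_grid(path)
  expect_equal(back$x_mm, g$x_mm)
  expect_equal(back$values, g$values, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$meta$seed, g$meta$seed)
})
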