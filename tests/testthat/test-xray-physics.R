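# spectrum synthesis, attenuation data and filtering

test_that("critical energy follows the closed-form dipole relation", {
  expect_equal(critical_energy(syrmep_ring()), 0.665 * 2.4^2 * 1.45,
               tolerance = 1e-12)
  # cross-check value derived from the standard relation
  expect_equal(critical_energy(syrmep_ring()), 5.554, tolerance = 1e-3)
  # E^2 scaling
  expect_equal(critical_energy(ring_parameters(4.8, 1.45, 160)),
               4 * critical_energy(syrmep_ring()), tolerance = 1e-12)
  expect_error(ring_parameters(2.4, 0, 160), "positive")
  expect_error(ring_parameters(-1, 1.45, 160), "positive")
})

test_that("bending-magnet spectrum is smooth, unimodal and linear in current", {
  grid <- seq(5, 150, by = 1)
  s1 <- bending_magnet_spectrum(ring_parameters(2.4, 1.45, 160), grid)
  s2 <- bending_magnet_spectrum(ring_parameters(2.4, 1.45, 320), grid)
  expect_true(all(s1$flux_density >= 0))
  expect_equal(s2$flux_density / s1$flux_density, rep(2, length(grid)),
               tolerance = 1e-10)
  # unimodal: at most one sign change of the derivative (the per-keV
  # maximum sits at or below the low-energy end of this grid)
  d <- diff(s1$flux_density)
  expect_lte(sum(diff(sign(d[d != 0])) != 0), 1)
  expect_error(bending_magnet_spectrum(syrmep_ring(), numeric(0)),
               "empty")
})

test_that("flux far above the critical energy is strongly suppressed", {
  ec <- critical_energy(syrmep_ring())
  s <- bending_magnet_spectrum(syrmep_ring(), c(ec, 10 * ec))
  # universal spectral shape: G1(10)/G1(1) ~ 2e-4, well below 1e-2
  expect_lt(s$flux_density[2] / s$flux_density[1], 1e-2)
})

test_that("embedded attenuation tables match published reference values", {
  # frozen reference points (cm^2/g, total with coherent) at 10/30/60/100
  # keV from a standard published tabulation
  ref <- list(
    water = c(`10` = 5.329, `30` = 0.3756, `60` = 0.2059, `100` = 0.1707),
    aluminium = c(`10` = 26.23, `30` = 1.128, `60` = 0.2778,
                  `100` = 0.1704),
    beryllium = c(`10` = 0.6466, `30` = 0.1792, `60` = 0.1493,
                  `100` = 0.1328),
    air = c(`10` = 5.120, `30` = 0.3538, `60` = 0.1875, `100` = 0.1541),
    tungsten = c(`10` = 96.91, `30` = 22.73, `60` = 3.713, `100` = 4.438))
  for (mat in names(ref)) {
    e <- as.numeric(names(ref[[mat]]))
    got <- attenuation_coefficient(mat, e, "total")
    expect_equal(got, unname(ref[[mat]]), tolerance = 0.02,
                 label = paste(mat, "total"))
  }
})

test_that("attenuation interpolation and partial structure are consistent", {
  tab <- material_table("water")
  # interpolation identity at a table node
  i <- 20
  expect_equal(attenuation_coefficient("water", tab$energy_keV[i]),
               tab$total[i], tolerance = 1e-12)
  # partials sum to total and never exceed it
  for (mat in supported_materials()) {
    e <- c(10.5, 25, 47, 93, 140)
    tot <- attenuation_coefficient(mat, e, "total")
    parts <- sapply(c("photoelectric", "incoherent", "coherent"),
                    function(k) attenuation_coefficient(mat, e, k))
    expect_equal(rowSums(parts), tot, tolerance = 0.02)
    expect_true(all(parts > 0))
    expect_true(all(parts <= tot * (1 + 1e-9)))
  }
  expect_error(attenuation_coefficient("water", 2), "range")
  expect_error(attenuation_coefficient("gold", 30))
})

test_that("filter transmission behaves like an exponential stack", {
  e <- c(10, 30, 60)
  expect_equal(filter_transmission(list(), e), rep(1, 3))
  expect_equal(filter_transmission(list(filter_element("aluminium", 0)), e),
               rep(1, 3))
  # hand computation from the validated Al table: 3.5 mm at 30 keV
  t_al <- filter_transmission(list(filter_element("aluminium", 3.5)), 30)
  expect_equal(t_al, exp(-1.128 * 2.699 * 0.35), tolerance = 0.02)
  expect_equal(t_al, 0.34, tolerance = 0.02)
  # stacking order irrelevant, and adding a filter never increases it
  fl <- default_filters()
  expect_equal(filter_transmission(fl, e),
               filter_transmission(rev(fl), e))
  expect_true(all(filter_transmission(fl, e) <=
                    filter_transmission(fl[1], e)))
  expect_error(filter_element("aluminium", -1), "non-negative")
})

test_that("filtering hardens the beam and preserves the grid", {
  raw <- bending_magnet_spectrum(syrmep_ring())
  filt <- apply_filters(raw, default_filters())
  expect_identical(filt$energy_kev, raw$energy_kev)
  expect_true(all(filt$flux_density <= raw$flux_density))
  expect_identical(apply_filters(raw, list())$flux_density,
                   raw$flux_density)
  expect_gt(mean_energy(filt), mean_energy(raw))
  # filtered beamline spectrum peaks in the 20-40 keV band
  peak_e <- filt$energy_kev[which.max(filt$flux_density)]
  expect_gt(peak_e, 20)
  expect_lt(peak_e, 40)
})

test_that("mean energy is a flux-weighted first moment", {
  e <- seq(10, 50, by = 1)
  f <- rep(0, length(e))
  f[e == 30] <- 7
  sp <- photon_spectrum(e, f)
  expect_equal(mean_energy(sp), 30, tolerance = 1e-9)
  # invariant under uniform rescaling
  sp2 <- photon_spectrum(e, f * 42)
  expect_equal(mean_energy(sp2), mean_energy(sp))
  expect_error(mean_energy(photon_spectrum(e, rep(0, length(e)))), "zero")
  # power weighting shifts the mean upward
  filt <- beamline_spectrum()
  expect_gt(mean_energy(filt, "power"), mean_energy(filt, "flux"))
})

test_that("spectral sampling reproduces the spectrum", {
  sp <- beamline_spectrum()
  x1 <- sample_energies(sp, 1e5, seed = 42)
  expect_lt(abs(mean(x1) - mean_energy(sp)), 0.5)
  # fixed seed gives identical sequences
  expect_identical(x1, sample_energies(sp, 1e5, seed = 42))
  # single nonzero bin collapses to that energy
  e <- seq(10, 50, by = 1)
  f <- rep(0, length(e)); f[21] <- 1
  xs <- sample_energies(photon_spectrum(e, f), 100, seed = 1)
  expect_true(all(abs(xs - 30) <= 1))
})

test_that("spectrum I/O round-trips through delimited text", {
  sp <- beamline_spectrum(energy_kev = seq(5, 150, by = 5))
  path <- tempfile(fileext = ".tsv")
  write_spectrum(sp, path)
  back <- read_spectrum(path)
  expect_equal(back$energy_kev, sp$energy_kev)
  expect_equal(back$flux_density, sp$flux_density, tolerance = 1e-10)
})
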