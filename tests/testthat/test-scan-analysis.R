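# scanned fields, normalization and profile / PVDR analysis

test_that("surface dose formula reproduces the scan dose", {
  expect_equal(surface_dose(1.5, 1.638, 70), 1.5 / 1.638 * 70)
  expect_equal(surface_dose(1.5, 1.638, 70), 64.1, tolerance = 1e-3)
  expect_equal(surface_dose(1, 1, 1), 1)
  # doubling the speed halves the dose
  expect_equal(surface_dose(1.5, 2 * 1.638, 70),
               surface_dose(1.5, 1.638, 70) / 2)
  expect_error(surface_dose(1.5, 0, 70))
})

test_that("scanned field is a shift superposition: flat, linear, halo-preserving", {
  # synthetic static field: one x column with a Gaussian envelope plus a
  # wide scatter pedestal
  y <- seq(-5.95, 5.95, by = 0.1)
  x <- seq(-0.1, 0.1, by = 0.005)
  env <- exp(-y^2 / (2 * 0.637^2)) + 0.01 * exp(-y^2 / (2 * 3^2))
  vals <- outer(rep(1, length(x)), env)
  g <- dose_grid(x, y, vals)
  sc <- scanned_field(g, scan_config())
  # vertical flatness over the central 1 mm, well below 2% relative sd
  mid <- abs(sc$y_mm) <= 0.5
  flat <- sc$values[1, mid]
  expect_lt(stats::sd(flat) / mean(flat), 0.02)
  # every central value equals the full vertical integral per step (up
  # to half-voxel edge interpolation)
  expect_equal(mean(flat), sum(env), tolerance = 1e-3)
  # linearity: scanning a doubled field doubles the result
  g2 <- dose_grid(x, y, 2 * vals)
  expect_equal(scanned_field(g2, scan_config())$values, 2 * sc$values)
  # a coarse step triggers the ripple warning
  expect_warning(scanned_field(g, scan_config(step_um = 2000)), "coarse")
})

test_that("scanned microbeam field has its highest valley in the centre", {
  g <- run_static_field(small_transport(n = 1.5e5, seed = 41),
                        grid = grid_spec(x_pitch_um = 5, y_pitch_um = 200,
                                         x_half_mm = 4.3, y_half_mm = 8))
  sc <- scanned_field(g)
  prof <- horizontal_profile(sc, vertical_window_mm = 0.5)
  centres <- suppressWarnings(detect_peaks(prof, 400))
  vl <- valley_dose(prof, centres)$per_valley
  inner <- abs(vl$centre_mm) < 1
  outer_v <- abs(vl$centre_mm) > 2.5
  expect_gt(mean(vl$dose[inner]), mean(vl$dose[outer_v]))
})

test_that("normalization anchors the central peak and preserves PVDR", {
  cp <- comb_profile(peak = 2, valley = 0.02)
  g <- cp$grid
  an0 <- analyze_field(g, vertical_window_mm = 2)
  nm <- normalize_absolute(g, measured_peak_dose_gy = 65,
                           vertical_window_mm = 2)
  expect_equal(nm$meta$normalization$scale, 65 / 2, tolerance = 1e-9)
  an1 <- analyze_field(nm, vertical_window_mm = 2)
  expect_equal(an1$peak$dose, 65, tolerance = 1e-9)
  # PVDR invariant under the rescaling
  expect_equal(an1$pvdr_result$pvdr, an0$pvdr_result$pvdr,
               tolerance = 1e-12)
  g0 <- dose_grid(g$x_mm, g$y_mm, matrix(0, length(g$x_mm), 2))
  expect_error(normalize_absolute(g0), "peak")
})

test_that("horizontal profile averages correctly and propagates errors", {
  x <- seq(-1, 1, by = 0.01)
  y <- seq(-0.45, 0.45, by = 0.1)
  vals <- matrix(3, length(x), length(y))
  errs <- matrix(0.2, length(x), length(y))
  g <- dose_grid(x, y, vals, errs)
  p1 <- horizontal_profile(g, vertical_window_mm = 1)
  expect_true(all(p1$dose == 3))
  # stderr shrinks as 1/sqrt(rows) for independent voxels
  expect_equal(p1$stderr[1], 0.2 / sqrt(length(y)), tolerance = 1e-12)
  # a one-row window returns that row
  p2 <- horizontal_profile(g, vertical_window_mm = 0.1, centre_mm = 0.05)
  expect_equal(p2$dose, vals[, 6], ignore_attr = TRUE)
  expect_error(horizontal_profile(g, vertical_window_mm = 0.001,
                                  centre_mm = 3), "window")
})

test_that("peak detection finds a 20-beam comb to sub-voxel accuracy", {
  cp <- comb_profile()
  centres <- detect_peaks(cp$profile, 400)
  expect_length(centres, 20)
  expect_lt(max(abs(centres - cp$centres)), 2.5e-3)  # < 2.5 um
  # centres invariant under uniform rescaling
  g2 <- dose_grid(cp$grid$x_mm, cp$grid$y_mm, cp$grid$values * 17)
  centres2 <- detect_peaks(horizontal_profile(g2, 2), 400)
  expect_equal(centres2, centres)
  # flat profile is rejected
  flat <- dose_grid(cp$grid$x_mm, cp$grid$y_mm,
                    matrix(1, length(cp$grid$x_mm), 2))
  expect_error(detect_peaks(horizontal_profile(flat, 2), 400), "flat|peak")
})

test_that("peak and valley region doses follow their definitions", {
  cp <- comb_profile(peak = 65, valley = 0)
  pk <- peak_dose(cp$profile, cp$centres)
  # rectangular 50 um beams of height 65: the +-20 um region mean is 65
  expect_equal(pk$dose, 65, tolerance = 1e-9)
  vl <- valley_dose(cp$profile, cp$centres)
  expect_equal(vl$dose, 0)
  # triangular peak: pooled region mean is below the apex
  x <- seq(-0.2, 0.2, by = 0.005)
  tri <- pmax(1 - abs(x) / 0.05, 0)
  gt <- dose_grid(x, c(-0.5, 0.5), cbind(tri, tri))
  pt <- peak_dose(horizontal_profile(gt, 2), 0)
  expect_lt(pt$dose, 1)
  # constant field: valley equals peak, PVDR 1
  cf <- dose_grid(cp$grid$x_mm, cp$grid$y_mm,
                  matrix(5, length(cp$grid$x_mm), 2))
  pf <- horizontal_profile(cf, 2)
  expect_equal(pvdr(peak_dose(pf, cp$centres),
                    valley_dose(pf, cp$centres))$pvdr, 1)
  expect_error(valley_dose(cp$profile, cp$centres[1]), "2")
  expect_error(valley_dose(cp$profile, cp$centres, valley_window_um = 500),
               "overlap")
})

test_that("PVDR propagates errors and degrades under contamination", {
  res <- pvdr(list(dose = 65, stderr = 0.5), list(dose = 0.53,
                                                  stderr = 0.02))
  expect_equal(res$pvdr, 65 / 0.53, tolerance = 1e-12)
  expect_equal(res$pvdr, 123, tolerance = 0.005)
  rel <- sqrt((0.5 / 65)^2 + (0.02 / 0.53)^2)
  expect_equal(res$stderr, res$pvdr * rel, tolerance = 1e-12)
  # adding a constant background strictly lowers the PVDR
  res_bg <- pvdr(66, 1.53)
  expect_lt(res_bg$pvdr, res$pvdr)
  # global rescaling leaves it unchanged
  expect_equal(pvdr(650, 5.3)$pvdr, pvdr(65, 0.53)$pvdr)
  expect_true(pvdr(65, 0)$lower_bound_only)
})
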