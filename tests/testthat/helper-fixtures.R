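# shared small fixtures; everything is built in code at test time

syrmep_ring <- function() ring_parameters(2.4, 1.45, 160)

small_transport <- function(n = 5e4, seed = 11, ...) {
  transport_config(n_histories = n, seed = seed, batches = 5, ...)
}

# coarse grid for fast MC tests
small_grid <- function() grid_spec(x_pitch_um = 5, y_pitch_um = 200,
                                   x_half_mm = 2.2, y_half_mm = 8)

# a narrow collimator (few slits) to keep ray/MC tests cheap
small_msc <- function(n_slits = 8) collimator_spec(n_slits = n_slits)

# brute-force fine-step march of a ray through the lamella comb
path_march_oracle <- function(x_in, slope, msc, step_um = 0.1) {
  step <- step_um / 1000
  z <- seq(step / 2, msc$depth_mm - step / 2, by = step)
  xs <- x_in + slope * z
  ctr <- (seq_len(msc$n_slits) - (msc$n_slits + 1) / 2) *
    msc$pitch_um / 1000
  w <- msc$slit_width_um / 2000
  open <- rep(FALSE, length(xs))
  for (c0 in ctr) open <- open | abs(xs - c0) <= w
  sum(!open) * step * sqrt(1 + slope^2)
}

# synthetic rectangular-comb dose profile with known truth
comb_profile <- function(n_beams = 20, pitch_um = 400, width_um = 50,
                         peak = 65, valley = 0.5, pitch_x_um = 5,
                         half_mm = 4.5) {
  x <- seq(-half_mm, half_mm, by = pitch_x_um / 1000)
  ctr <- (seq_len(n_beams) - (n_beams + 1) / 2) * pitch_um / 1000
  d <- rep(valley, length(x))
  for (c0 in ctr) d[abs(x - c0) <= width_um / 2000] <- peak
  g <- dose_grid(x, c(-0.5, 0.5), cbind(d, d))
  list(profile = horizontal_profile(g, vertical_window_mm = 2),
       centres = ctr, grid = g)
}
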