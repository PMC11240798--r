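test_that("raised-cosine waveform spans [0, 1] exactly for even phase counts", {
  for (P in c(4, 10, 12)) {
    w <- raised_cosine((seq_len(P) - 1) / P)
    expect_equal(min(w), 0)
    expect_equal(max(w), 1)
  }
})

test_that("phantom config validates its invariants", {
  expect_error(phantom_config(n_phases = 2), "at least 3")
  expect_error(phantom_config(slice_zs = c(0, 0, 1)), "strictly increasing")
  expect_error(phantom_config(vertex_step = 0.7), "divisor of 360")
  expect_error(phantom_config(noise_sd = -1), "non-negative")
})

test_that("lag-free phantom truth is R = 1 and magnitude = amplitude", {
  cfg <- small_config(amplitude_field = function(theta, z)
    rep_len(5, length(theta)))
  torso <- generate_torso(cfg)
  expect_equal(torso$truth$correlation_truth,
               matrix(1, 10, 180), tolerance = 1e-12)
  expect_equal(torso$truth$magnitude_truth,
               matrix(5, 10, 180), tolerance = 1e-12)
})

test_that("anti-phase lag flips the correlation truth to -1", {
  cfg <- small_config(lag_field = function(theta, z)
    rep_len(0.5, length(theta)))
  torso <- generate_torso(cfg)
  expect_equal(torso$truth$correlation_truth,
               matrix(-1, 10, 180), tolerance = 1e-12)
})

test_that("a motionless phantom has zero magnitude and undefined correlation", {
  cfg <- small_config(amplitude_field = function(theta, z)
    rep_len(0, length(theta)))
  torso <- generate_torso(cfg)
  expect_true(all(torso$truth$magnitude_truth == 0))
  expect_true(all(is.na(torso$truth$correlation_truth)))
})

test_that("phantom generation is deterministic under a fixed seed", {
  cfg <- small_config(noise_sd = 1, seed = 11L)
  a <- generate_torso(cfg)
  b <- generate_torso(cfg)
  expect_identical(a, b)
  cfg2 <- small_config(noise_sd = 1, seed = 12L)
  expect_false(identical(generate_torso(cfg2)$phases, a$phases))
})

test_that("a torso with non-positive radius is rejected", {
  cfg <- small_config(base_radius = function(theta, z)
                        rep_len(2, length(theta)),
                      amplitude_field = function(theta, z)
                        rep_len(5, length(theta)),
                      lag_field = function(theta, z)
                        rep_len(0.5, length(theta)))
  # at the lag-shifted waveform peak the radius would need to be positive;
  # here the noise-free radius stays positive, so shrink with noise instead
  cfg2 <- small_config(base_radius = function(theta, z)
                         rep_len(0.5, length(theta)),
                       amplitude_field = function(theta, z)
                         rep_len(0, length(theta)),
                       noise_sd = 5, seed = 3L)
  expect_error(generate_torso(cfg2), "non-positive")
  expect_silent(invisible(generate_torso(cfg)))
})

test_that("TS trajectory follows the waveform with the configured excursion", {
  cfg <- small_config(ts_amplitude = 8, ts_base_z = 250)
  ts <- generate_ts(cfg)
  expect_length(ts$z_per_phase, 10)
  expect_equal(max(ts$z_per_phase) - min(ts$z_per_phase), 8)
  # peak inhale at p = 5 for P = 10; inhalation displacement is positive
  expect_equal(ts$z_per_phase[6], 250 + 8)
  expect_equal(ts$z_per_phase[1], 250)

  still <- generate_ts(small_config(ts_amplitude = 0))
  expect_equal(ts_magnitude(still), 0)
})

test_that("L4 phantom analytic areas follow ellipse and circle geometry", {
  cfg <- small_config()
  l4 <- generate_l4_slice(cfg, body = c(150, 100), sat_inner = c(140, 92),
                          n_blobs = 0L)
  expect_equal(l4$truth$sat_area, pi * (150 * 100 - 140 * 92))
  expect_equal(l4$truth$vat_area, 0)
  expect_equal(l4$truth$tat_area, l4$truth$sat_area)
  expect_error(generate_l4_slice(cfg, body = c(100, 80),
                                 sat_inner = c(110, 70)),
               "nested")
})

test_that("pixel-counted phantom areas agree with the analytic areas within 2%", {
  l4 <- generate_l4_slice(small_config(seed = 5L))
  tat <- adipose_mask(l4$slice)
  sv <- split_sat_vat(tat, l4$inner_wall, l4$slice)
  px <- prod(l4$slice$pixel_spacing)
  expect_equal(sum(sv$sat) * px, l4$truth$sat_area,
               tolerance = 0.02)
  expect_equal(sum(sv$vat) * px, l4$truth$vat_area,
               tolerance = 0.02)
  expect_equal(sum(l4$slice$body_mask) * px, l4$truth$body_area,
               tolerance = 0.02)
})
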