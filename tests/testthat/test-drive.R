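# helper: wrap a raw grid as a receptive_field-like object for kernels
# that are not Gabors (identity/difference filters used as oracles)
manual_rf <- function(grid, channels, sigma_f = 1000, lag_step = 1e-3) {
  p <- rf_params(t0 = 0.001, f0 = channels[1], sigma_t = 1e-3,
                 sigma_f = sigma_f)
  structure(list(grid = grid, params = p, lag_step = lag_step,
                 channel_centers = channels, norm = "none",
                 norm_applied = "none", norm_divisor = 1),
            class = "receptive_field")
}

manual_spec <- function(mat, channels, frame_step = 1e-3) {
  structure(list(matrix = mat, frame_step = frame_step,
                 channel_centers = channels, scale_mode = "linear",
                 syllables = NULL, label = "toy"),
            class = "spectrogram")
}

test_that("impulse kernel delays a spectrogram channel", {
  ch <- default_channels()
  grid <- matrix(0, nrow = 10, ncol = 50)
  grid[4, 7] <- 1                         # lag 3 frames, channel 7
  set.seed(2)
  S <- matrix(rnorm(100 * 50), 100, 50)
  rf <- manual_rf(grid, ch, sigma_f = 1000)   # sigma_f_khz = 1
  d <- convolve_drive(rf, manual_spec(S, ch), gain = 1, center = FALSE)
  expect_equal(d$i_stim[4:100], S[1:97, 7], tolerance = 1e-12)
  expect_equal(d$i_stim[1:3], rep(0, 3))
})

test_that("two-frame difference kernel matches the hand convolution", {
  ch <- 100
  grid <- matrix(c(1, -1), nrow = 2, ncol = 1)
  S <- matrix(c(0, 1, 1, 0), ncol = 1)
  rf <- manual_rf(grid, ch, sigma_f = 1000)
  d <- convolve_drive(rf, manual_spec(S, ch), gain = 1, center = FALSE)
  expect_equal(d$i_stim, c(0, 1, 0, -1))
})

test_that("zero spectrogram yields zero current and linearity holds", {
  ch <- default_channels()
  rf <- build_rf(rf_params(0.02, 3000, 0.008, 600, omega_t = 20))
  zero <- manual_spec(matrix(0, 200, 50), ch)
  expect_true(all(convolve_drive(rf, zero)$i_stim == 0))
  set.seed(4)
  S <- matrix(rnorm(200 * 50), 200, 50)
  d1 <- convolve_drive(rf, manual_spec(S, ch), center = FALSE)$i_stim
  d3 <- convolve_drive(rf, manual_spec(3 * S, ch), center = FALSE)$i_stim
  expect_equal(d3, 3 * d1, tolerance = 1e-9)
})

test_that("channel mismatch is rejected", {
  rf <- build_rf(rf_params(0.02, 3000, 0.008, 600))
  sp <- manual_spec(matrix(0, 50, 40), default_channels(40))
  expect_error(convolve_drive(rf, sp), "channels")
})

test_that("noise PSD follows 1/f^alpha and the SNR scaling is exact", {
  n <- 2^16
  dt <- 1e-3
  slope <- function(alpha) {
    x <- make_noise(n, dt, noise_spec(alpha = alpha, snr = 4, seed = 5),
                    signal_rms = 100)
    ps <- Mod(fft(x))^2
    freq <- (seq_len(n) - 1) / (n * dt)
    keep <- freq >= 1 & freq <= 100
    unname(coef(lm(log10(ps[keep]) ~ log10(freq[keep])))[2])
  }
  expect_equal(slope(2), -2, tolerance = 0.3)
  expect_equal(slope(0), 0, tolerance = 0.3)

  for (alpha in c(0, 1, 2)) {
    x <- make_noise(5000, dt, noise_spec(alpha = alpha, snr = 4, seed = 9),
                    signal_rms = 100)
    expect_equal(sqrt(mean(x^2)), 25, tolerance = 1e-6)
    expect_equal(mean(x), 0, tolerance = 1e-9)
  }
  # power convention: RMS ratio is sqrt(snr)
  x <- make_noise(5000, dt, noise_spec(2, 4, 9, convention = "power"),
                  signal_rms = 100)
  expect_equal(sqrt(mean(x^2)), 50, tolerance = 1e-6)
})

test_that("differenced red noise has an approximately flat spectrum", {
  x <- make_noise(2^15, 1e-3, noise_spec(alpha = 2, snr = 4, seed = 13),
                  signal_rms = 100)
  dx <- diff(x)
  ps <- Mod(fft(dx))^2
  freq <- (seq_along(dx) - 1) / (length(dx) * 1e-3)
  keep <- freq >= 1 & freq <= 100
  sl <- unname(coef(lm(log10(ps[keep]) ~ log10(freq[keep])))[2])
  expect_equal(sl, 0, tolerance = 0.5)
})

test_that("paired noise seeds ignore dynamics and separate trials", {
  ns <- noise_spec(alpha = 2, snr = 4, seed = 77)
  s1 <- pair_trial_noise(ns, rf_id = 3, stim_id = 2, trial_index = 1)
  s2 <- pair_trial_noise(ns, rf_id = 3, stim_id = 2, trial_index = 1)
  expect_identical(s1, s2)   # no dependence on anything but (rf,stim,trial)
  expect_false(pair_trial_noise(ns, 3, 2, 2) == s1)
  expect_false(pair_trial_noise(ns, 4, 2, 1) == s1)
  x1 <- make_noise(100, 1e-3, ns, 100, seed = s1)
  x2 <- make_noise(100, 1e-3, ns, 100, seed = s1)
  expect_identical(x1, x2)
})

test_that("invalid noise specifications error", {
  expect_error(noise_spec(snr = 0), "snr")
  expect_error(noise_spec(alpha = -1), "alpha")
  expect_error(make_noise(1, 1e-3, noise_spec()), "at least 2")
})

test_that("per-RF calibration hits the target SD for each RF", {
  stims <- lapply(1:2, function(i)
    generate_synthetic_song(seed = i, n_syllables = 4, duration = 1,
                            label = paste0("s", i)))
  specs <- lapply(stims, compute_spectrogram)
  rfs <- lapply(sample_rf_ensemble(3, seed = 2), build_rf)
  g <- calibrate_gain(rfs, specs, target_sd = 200)
  expect_length(g, 3)
  for (i in 1:3) {
    pooled <- unlist(lapply(specs, function(sp)
      convolve_drive(rfs[[i]], sp, gain = g[i])$i_stim))
    expect_equal(sd(pooled), 200, tolerance = 1e-6)
  }
  gs <- calibrate_gain(rfs, specs, target_sd = 200, per_rf = FALSE)
  expect_length(gs, 1)
})
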