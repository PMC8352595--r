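test_that("per-pixel power spectra match a brute-force DFT", {
  set.seed(11)
  for (T in c(16, 32)) {
    fr <- array(runif(3 * 3 * T, 0, 255), c(3, 3, T))
    field <- pixel_power_spectra(time_lapse_stack(fr, 250))
    for (px in c(1, 5, 9)) {
      i <- (px - 1) %% 3 + 1; j <- (px - 1) %/% 3 + 1
      expect_equal(field$power[px, ], brute_dft_power(fr[i, j, ]),
                   tolerance = 1e-9)
    }
    expect_equal(field$freq, (0:(T / 2)) * 250 / T)
  }
})

test_that("constant and exact-bin sinusoid series have canonical spectra", {
  fr <- array(7, c(2, 2, 64))
  field <- pixel_power_spectra(time_lapse_stack(fr, 250))
  expect_true(all(field$power[, -1] == 0))
  # 20 Hz sinusoid at 250 Hz over 250 frames sits exactly on bin 20
  sim <- sinusoid_stack(freq = 20, acq = 250, T = 250, H = 4, W = 4)
  field <- pixel_power_spectra(sim$stack)
  bin20 <- which(field$freq == 20)
  nondc <- field$power[, -1]
  # quantisation to integer intensities leaves only crumbs off-peak
  expect_true(all(field$power[, bin20] / rowSums(nondc) > 0.99))
})

test_that("spectral smoothing is a shrinking-window moving average", {
  T <- 40; acq <- 20  # spacing 0.5 Hz
  fr <- array(rnorm(4 * T, 100, 5), c(2, 2, T))
  field <- pixel_power_spectra(time_lapse_stack(fr, acq))
  # flat spectrum is unchanged
  flat <- field; flat$power <- matrix(3, 4, length(field$freq))
  sm <- smooth_spectra(flat, 2.5)  # 5 bins
  expect_equal(sm$power, flat$power)
  expect_equal(sm$smooth_bins, 5L)
  # interior unit impulse spreads to five bins of 0.2
  imp <- field; imp$power <- matrix(0, 4, length(field$freq))
  imp$power[, 10] <- 1
  sm <- smooth_spectra(imp, 2.5)
  expect_equal(sm$power[1, 8:12], rep(0.2, 5))
  expect_equal(sum(sm$power[1, ]), 1)  # power conserved (interior support)
  # edge bins average over what exists
  edge <- field; edge$power <- matrix(0, 4, length(field$freq))
  edge$power[, 1] <- 1
  sm <- smooth_spectra(edge, 2.5)
  expect_equal(sm$power[1, 1], 1 / 3)  # window shrinks to bins 1..3
  expect_error(smooth_spectra(field, 0.1), "at least one frequency bin")
})

test_that("primary peaks respect the range and tie rules", {
  T <- 100; acq <- 250
  fr <- array(0, c(2, 2, T))
  field <- pixel_power_spectra(time_lapse_stack(fr + 1, acq))
  params <- cbf_params(acq)
  # peaks at 2.5 Hz (power 10, out of range) and 20 Hz (power 5)
  field$power <- matrix(0, 4, length(field$freq))
  field$power[, which(field$freq == 2.5)] <- 10
  field$power[, which(field$freq == 20)] <- 5
  pk <- primary_peak_map(field, params)
  expect_true(all(pk$frequency == 20))
  expect_true(all(pk$power == 5))
  # all-zero spectrum falls to the lowest in-range bin, power 0
  field$power[] <- 0
  pk <- primary_peak_map(field, params)
  fmin_bin <- min(field$freq[field$freq >= params$f_min])
  expect_true(all(pk$frequency == fmin_bin))
  expect_true(all(pk$power == 0))
  # a genuine sinusoid pixel peaks at its own frequency (1-bin window;
  # a wider flat window turns an exact-bin tone into a plateau whose
  # argmax can sit anywhere within half the window)
  sim <- sinusoid_stack(freq = 20, T = 250, H = 4, W = 4)
  raw <- pixel_power_spectra(sim$stack)
  sf <- smooth_spectra(raw, raw$freq[2] - raw$freq[1])
  pk <- primary_peak_map(sf, cbf_params(250))
  expect_true(all(pk$frequency == 20))
  sf5 <- smooth_spectra(raw, 5)  # 5-bin window: plateau of half-width 2 Hz
  pk5 <- primary_peak_map(sf5, cbf_params(250))
  expect_true(all(abs(pk5$frequency - 20) <= 2))
  expect_error(primary_peak_map(field, cbf_params(250, f_min = 101,
                                                  f_max = 102)),
               "no frequency bins")
})

test_that("signal/noise classification follows the threshold rule", {
  params <- cbf_params(250)
  mk_peaks <- function(pw, H, W) {
    structure(list(frequency = matrix(10, H, W),
                   power = matrix(pw, H, W), dim = c(H, W)),
              class = "peak_map")
  }
  # identical powers: SD 0, threshold = the power, strictly-above = none
  cls <- classify_signal_noise(mk_peaks(rep(4, 25), 5, 5), params)
  expect_equal(cls$power_threshold, 4)
  expect_equal(sum(cls$signal_mask), 0)
  # hand case: 20 zeros then 80 pixels at 100; the bottom 20% is exactly
  # the zeros -> threshold 0, 80 signal pixels
  cls <- classify_signal_noise(mk_peaks(c(rep(0, 20), rep(100, 80)),
                                        10, 10), params)
  expect_equal(cls$power_threshold, 0)
  expect_equal(sum(cls$signal_mask), 80)
  # with only 4 zeros the bottom 20 pixels mix in sixteen 100s:
  # mean 80, population SD 40 -> threshold 140, nothing above it
  cls <- classify_signal_noise(mk_peaks(c(rep(0, 4), rep(100, 96)),
                                        10, 10), params)
  expect_equal(cls$power_threshold, 80 + 1.5 * 40)
  expect_equal(sum(cls$signal_mask), 0)
  # scale equivariance
  set.seed(3)
  pw <- rexp(100)
  a <- classify_signal_noise(mk_peaks(pw, 10, 10), params)
  b <- classify_signal_noise(mk_peaks(2 * pw, 10, 10), params)
  expect_equal(b$power_threshold, 2 * a$power_threshold)
  expect_equal(b$signal_mask, a$signal_mask)
  expect_error(classify_signal_noise(mk_peaks(1:4, 2, 2), params),
               "at least 5 pixels")
})

test_that("noise reference spectrum is per-bin mean + k SD", {
  params <- cbf_params(250)
  field <- structure(list(power = rbind(c(0, 1), c(2, 1)),
                          freq = c(0, 1), dim = c(2, 1),
                          acquisition_frequency = 250),
                     class = "spectrum_field")
  mask <- matrix(c(TRUE, TRUE), 2, 1)
  ns <- noise_reference_spectrum(field, mask, params)
  expect_equal(ns, c(1 + 1.5 * 1, 1))  # population SD of {0,2} is 1
  expect_true(all(ns >= colMeans(field$power)))
  # a single shared spectrum comes back unchanged (SD 0)
  field$power <- rbind(c(3, 5), c(3, 5))
  expect_equal(noise_reference_spectrum(field, mask, params), c(3, 5))
  expect_error(noise_reference_spectrum(field, mask & FALSE, params),
               "no noise pixels")
})

test_that("noise-corrected cell spectrum yields the CBF", {
  sim <- sinusoid_stack(freq = 22.4609375, T = 512, H = 4, W = 4)
  raw <- pixel_power_spectra(sim$stack)
  field <- smooth_spectra(raw, raw$freq[2] - raw$freq[1])  # 1-bin window
  params <- cbf_params(250)
  mask <- matrix(FALSE, 16, 1); mask[1] <- TRUE
  field$dim <- c(16L, 1L)
  rep <- signal_spectrum_cbf(field, mask, rep(0, length(field$freq)),
                             params)
  expect_equal(rep$cbf_hz, 22.4609375)
  expect_equal(rep$n_signal_pixels, 1)
  # a dominating noise spectrum clamps everything to zero -> undefined
  big <- apply(field$power, 2, max) + 1
  rep <- signal_spectrum_cbf(field, mask, big, params)
  expect_false(rep$cbf_defined)
  expect_true(all(rep$cell_spectrum == 0))
  # no signal pixels -> undefined, flagged, not an error
  rep <- signal_spectrum_cbf(field, mask & FALSE, big, params)
  expect_false(rep$cbf_defined)
  expect_equal(rep$n_signal_pixels, 0)
})

test_that("corrected cell spectrum never exceeds the raw signal mean", {
  sim <- sinusoid_stack(freq = 22, T = 128, H = 6, W = 6)
  field <- smooth_spectra(pixel_power_spectra(sim$stack), 5)
  params <- cbf_params(250)
  mask <- matrix(TRUE, 36, 1)
  field$dim <- c(36L, 1L)
  ns <- rep(2, length(field$freq))
  rep <- signal_spectrum_cbf(field, mask, ns, params)
  expect_true(all(rep$cell_spectrum >= 0))
  expect_true(all(rep$cell_spectrum <= colMeans(field$power) + 1e-9))
})
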