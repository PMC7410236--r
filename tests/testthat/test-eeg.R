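make_sine <- function(freq, fs = 1000, dur = 30, amp = 50) {
  eeg_trace(amp * sin(2 * pi * freq * (0:(dur * fs - 1)) / fs), fs_hz = fs)
}

test_that("the band-pass keeps in-band tones and suppresses out-of-band ones", {
  inb <- bandpass(make_sine(2), 0.5, 300)
  expect_equal(stats::sd(inb$samples), stats::sd(make_sine(2)$samples),
               tolerance = 0.05)
  expect_equal(inb$band, c(0.5, 300))

  out <- bandpass(make_sine(400), 0.5, 300)
  atten_db <- 10 * log10(mean(make_sine(400)$samples^2) /
                           mean(out$samples^2))
  expect_gte(atten_db, 20)
  expect_error(bandpass(make_sine(2), 0.5, 600), "fs/2")
})

test_that("band-passed white noise carries little out-of-band power", {
  set.seed(30)
  tr <- eeg_trace(stats::rnorm(30000), fs_hz = 1000)
  filt <- bandpass(tr, 1, 100)
  sp <- power_spectrum(filt)
  oob <- sum(sp$power[sp$freqs_hz < 0.5 | sp$freqs_hz > 150])
  expect_lt(oob / sum(sp$power), 0.05)
})

test_that("spectral peaks land on the programmed tone frequencies", {
  sp <- power_spectrum(make_sine(2))
  expect_equal(sp$freqs_hz[which.max(sp$power)], 2, tolerance = 0.25 / 2)

  t <- (0:(30 * 1000 - 1)) / 1000
  two <- eeg_trace(50 * sin(2 * pi * 0.5 * t) + 50 * sin(2 * pi * 2 * t),
                   fs_hz = 1000)
  pk <- spectral_peaks(power_spectrum(two), n = 2, max_hz = 10)
  expect_equal(pk$freq_hz, c(0.5, 2.0), tolerance = 0.13)
})

test_that("width at mid-height recovers a constructed rectangular spectrum", {
  # equal-amplitude tones tiling 4-14 Hz: a 10 Hz-wide rectangular spectrum
  fs <- 1000; dur <- 60
  t <- (0:(dur * fs - 1)) / fs
  set.seed(31)
  x <- 0
  for (f in seq(4, 14, by = 0.25))
    x <- x + sin(2 * pi * f * t + stats::runif(1, 0, 2 * pi))
  sp <- power_spectrum(eeg_trace(x, fs_hz = fs))
  expect_equal(sp$whm_hz, 10, tolerance = 1 / 10)
})

test_that("amplitude distributions normalize and rank states by kurtosis", {
  set.seed(32)
  gauss <- eeg_trace(stats::rnorm(60000), fs_hz = 1000)
  ad <- amplitude_distribution(gauss)
  expect_equal(sum(ad$probability), 1)
  expect_equal(ad$excess_kurtosis, 0, tolerance = 0.2)

  pb <- generate_eeg(eeg_preset("pentobarbital", duration_s = 60, seed = 33))
  wake <- generate_eeg(eeg_preset("wake", duration_s = 60, seed = 33))
  expect_gt(amplitude_distribution(pb)$excess_kurtosis,
            amplitude_distribution(wake)$excess_kurtosis)
  expect_error(amplitude_distribution(eeg_trace(rep(1, 100))), "constant")
})

test_that("the spectrogram has the prescribed time grid and tracks ridges", {
  tr <- make_sine(2, dur = 60)
  sg <- eeg_spectrogram(tr)
  expect_length(sg$times_s, floor((60 - 4) / 0.5) + 1) # 113
  ridge <- sg$freqs_hz[apply(sg$log_amplitude, 2, which.max)]
  expect_true(all(abs(ridge - 2) <= 0.25))
  expect_error(eeg_spectrogram(make_sine(2, dur = 2)), "shorter")
})

test_that("the ketamine/xylazine 2 Hz ridge decays across the record", {
  kx <- generate_eeg(eeg_preset("ketamine_xylazine", duration_s = 120,
                                seed = 34))
  sg <- eeg_spectrogram(kx)
  i2 <- which.min(abs(sg$freqs_hz - 2))
  amp <- 10^sg$log_amplitude[i2, ]
  nq <- length(amp) %/% 4
  expect_lt(mean(amp[(length(amp) - nq + 1):length(amp)]),
            mean(amp[1:nq]))
})

test_that("rectangular-window spectra satisfy Parseval within 5%", {
  set.seed(35)
  x <- stats::rnorm(40000)
  sp <- power_spectrum(eeg_trace(x, fs_hz = 1000), window = "rect")
  expect_equal(sum(sp$power), stats::var(x), tolerance = 0.05)
})

test_that("the spectrogram time-marginal agrees with the Welch spectrum", {
  wake <- generate_eeg(eeg_preset("wake", duration_s = 60, seed = 36))
  sp <- power_spectrum(wake)
  sg <- eeg_spectrogram(wake)
  marg <- rowMeans((10^sg$log_amplitude)^2)
  # compare low-frequency band fractions of the two normalized spectra
  bf <- function(f, p, cut = 15) sum(p[f <= cut]) / sum(p)
  expect_equal(bf(sg$freqs_hz, marg), bf(sp$freqs_hz, sp$power),
               tolerance = 0.1)
})

test_that("the three presets separate in WHM / kurtosis / delta-fraction space", {
  feats <- lapply(1:10, function(s) {
    out <- list()
    for (st in c("wake", "ketamine_xylazine", "pentobarbital")) {
      tr <- generate_eeg(eeg_preset(st, duration_s = 40, seed = s))
      sp <- power_spectrum(tr)
      delta <- sum(sp$power[sp$freqs_hz <= 4]) / sum(sp$power)
      out[[st]] <- c(whm = sp$whm_hz,
                     kurt = amplitude_distribution(tr)$excess_kurtosis,
                     delta = delta)
    }
    out
  })
  for (f in feats) {
    # slow-wave anesthesia concentrates power below 4 Hz
    expect_gt(f$ketamine_xylazine["delta"], f$wake["delta"])
    # burst suppression is the heavy-tailed state
    expect_gt(f$pentobarbital["kurt"], f$wake["kurt"])
    expect_gt(f$pentobarbital["kurt"], f$ketamine_xylazine["kurt"])
    # wake keeps the broadest spectrum
    expect_gt(f$wake["whm"], f$ketamine_xylazine["whm"])
  }
})

test_that("EEG CSV round trip preserves the trace", {
  tr <- generate_eeg(eeg_preset("wake", duration_s = 3, seed = 37))
  path <- tempfile(fileext = ".csv")
  write_eeg_csv(tr, path)
  back <- read_eeg_csv(path)
  expect_equal(back$fs_hz, tr$fs_hz)
  expect_equal(back$samples, tr$samples, tolerance = 1e-6)
  unlink(path)
})
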