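#' Anesthesia-state EEG preset
#'
#' Parameterizes the synthetic single-channel EEG generator for the three
#' vigilance/anesthesia states profiled by the pipeline:
#' \describe{
#'   \item{wake}{broadband activity whose power spectrum has a Gaussian
#'     envelope with half-maximum at \code{wake_whm_hz}, so the measured
#'     spectral width at mid-height is ~\code{wake_whm_hz}.}
#'   \item{ketamine_xylazine}{a near-bichromatic slow-wave signal: large
#'     sinusoids at 0.5 and 2 Hz over low background noise, the 2 Hz
#'     component decaying linearly over the record.}
#'   \item{pentobarbital}{burst suppression: a near-isoelectric baseline
#'     interrupted by sporadic high-amplitude bursts.}
#' }
#'
#' @param state one of \code{"wake"}, \code{"ketamine_xylazine"},
#'   \code{"pentobarbital"}.
#' @param fs_hz sampling rate in Hz.
#' @param duration_s record duration in seconds.
#' @param seed RNG seed.
#' @param wake_whm_hz target spectral width at mid-height of the wake state.
#' @param kx_amp_uv amplitudes (0.5 Hz, 2 Hz) of the bichromatic components.
#' @param kx_decay_frac fraction of its initial amplitude the 2 Hz component
#'   retains at the end of the record (linear decay).
#' @param pb_burst_rate_hz expected burst rate of the pentobarbital state.
#' @param pb_burst_dur_s burst duration in seconds.
#' @param pb_burst_amp_uv burst peak amplitude.
#' @param baseline_noise_uv background noise SD (isoelectric floor for
#'   pentobarbital, additive noise otherwise).
#' @return An object of class \code{eeg_preset}.
#' @export
eeg_preset <- function(state = c("wake", "ketamine_xylazine", "pentobarbital"),
                       fs_hz = 1000, duration_s = 120, seed = 1,
                       wake_whm_hz = 10, kx_amp_uv = c(120, 90),
                       kx_decay_frac = 0.3, pb_burst_rate_hz = 0.12,
                       pb_burst_dur_s = 0.8, pb_burst_amp_uv = 180,
                       baseline_noise_uv = 6) {
  state <- match.arg(state)
  stopifnot(fs_hz > 0, duration_s > 0)
  structure(list(state = state, fs_hz = fs_hz, duration_s = duration_s,
                 seed = as.integer(seed), wake_whm_hz = wake_whm_hz,
                 kx_amp_uv = kx_amp_uv, kx_decay_frac = kx_decay_frac,
                 pb_burst_rate_hz = pb_burst_rate_hz,
                 pb_burst_dur_s = pb_burst_dur_s,
                 pb_burst_amp_uv = pb_burst_amp_uv,
                 baseline_noise_uv = baseline_noise_uv),
            class = "eeg_preset")
}

# Gaussian-noise trace whose power spectrum is flat at low frequency and
# rolls off steeply through half-maximum at whm_hz (12th-order-style
# shoulder), so the spectral width at mid-height is sharply defined at
# whm_hz. Frequency-domain shaping of white noise.
shaped_noise <- function(n, fs, whm_hz, sd_uv) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- c(seq(0, floor(n / 2)), seq(-(ceiling(n / 2) - 1), -1)) * fs / n
  X <- X / sqrt(1 + (f / whm_hz)^24)
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  y * sd_uv / stats::sd(y)
}

#' Generate a synthetic anesthesia-state EEG trace
#'
#' @param preset an [eeg_preset()].
#' @return An [eeg_trace()] of \code{duration_s * fs_hz} samples in microvolts,
#'   carrying the preset state as attribute \code{state}.
#' @export
#' @examples
#' tr <- generate_eeg(eeg_preset("ketamine_xylazine", duration_s = 30, seed = 2))
generate_eeg <- function(preset) {
  stopifnot(inherits(preset, "eeg_preset"))
  set.seed(preset$seed)
  fs <- preset$fs_hz
  n <- round(preset$duration_s * fs)
  t <- (seq_len(n) - 1) / fs

  x <- switch(preset$state,
    wake = shaped_noise(n, fs, preset$wake_whm_hz, sd_uv = 25),
    ketamine_xylazine = {
      decay <- seq(1, preset$kx_decay_frac, length.out = n)
      preset$kx_amp_uv[1] * sin(2 * pi * 0.5 * t + stats::runif(1, 0, 2 * pi)) +
        preset$kx_amp_uv[2] * decay *
          sin(2 * pi * 2 * t + stats::runif(1, 0, 2 * pi)) +
        stats::rnorm(n, 0, preset$baseline_noise_uv)
    },
    pentobarbital = {
      base <- stats::rnorm(n, 0, preset$baseline_noise_uv)
      n_burst <- stats::rpois(1, preset$pb_burst_rate_hz * preset$duration_s)
      wlen <- round(preset$pb_burst_dur_s * fs)
      if (n_burst > 0 && wlen > 1) {
        starts <- sort(sample.int(max(1, n - wlen), n_burst))
        env <- 0.5 * (1 - cos(2 * pi * seq_len(wlen) / (wlen + 1))) # Hann
        for (s in starts) {
          fb <- stats::runif(1, 3, 9) # intra-burst oscillation frequency
          ph <- stats::runif(1, 0, 2 * pi)
          idx <- s:(s + wlen - 1)
          base[idx] <- base[idx] + preset$pb_burst_amp_uv * env *
            sin(2 * pi * fb * (idx - s) / fs + ph)
        }
      }
      base
    })
  eeg_trace(x, fs_hz = fs, state = preset$state)
}
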