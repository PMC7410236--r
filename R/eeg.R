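#' Single-channel EEG trace container
#'
#' @param samples amplitude series in microvolts.
#' @param fs_hz sampling rate in Hz.
#' @param band applied filter band c(low, high) in Hz, or NULL if unfiltered.
#' @param state optional state label.
#' @return An object of class \code{eeg_trace}.
#' @export
eeg_trace <- function(samples, fs_hz = 1000, band = NULL, state = NULL) {
  stopifnot(fs_hz > 0, length(samples) >= 1)
  structure(list(samples = as.numeric(samples), fs_hz = fs_hz, band = band,
                 state = state), class = "eeg_trace")
}

#' @export
print.eeg_trace <- function(x, ...) {
  cat(sprintf("<eeg_trace> %.1f s at %g Hz%s%s\n",
              length(x$samples) / x$fs_hz, x$fs_hz,
              if (!is.null(x$band)) sprintf(", band [%g, %g] Hz",
                                            x$band[1], x$band[2]) else "",
              if (!is.null(x$state)) paste0(", state ", x$state) else ""))
  invisible(x)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a 4th-order Butterworth high-pass at \code{low_hz} and a
#' 4th-order Butterworth low-pass at \code{high_hz}, each forward-backward
#' (zero phase), so amplitude distributions are not skewed by phase
#' distortion. The applied band is recorded on the trace.
#'
#' @param trace an [eeg_trace()].
#' @param low_hz,high_hz band edges in Hz; must satisfy
#'   0 < low < high < fs/2.
#' @param order Butterworth order per section.
#' @return The filtered [eeg_trace()].
#' @export
bandpass <- function(trace, low_hz = 0.5, high_hz = 300, order = 4) {
  stopifnot(inherits(trace, "eeg_trace"))
  nyq <- trace$fs_hz / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    stop("band must satisfy 0 < low < high < fs/2")
  hp <- signal::butter(order, low_hz / nyq, type = "high")
  lp <- signal::butter(order, high_hz / nyq, type = "low")
  x <- signal::filtfilt(hp, trace$samples)
  x <- signal::filtfilt(lp, x)
  eeg_trace(x, fs_hz = trace$fs_hz, band = c(low_hz, high_hz),
            state = trace$state)
}

# Welch averaged periodogram. Power per one-sided frequency bin, scaled so
# that sum(power) equals the mean square of the (windowed-corrected) signal.
welch_psd <- function(x, fs, seg_s = 4, overlap = 0.5,
                      window = c("hann", "rect")) {
  window <- match.arg(window)
  nseg <- round(seg_s * fs)
  if (length(x) < nseg) stop("trace shorter than one estimation segment")
  step <- max(1, round(nseg * (1 - overlap)))
  starts <- seq(1, length(x) - nseg + 1, by = step)
  w <- if (window == "hann")
    0.5 * (1 - cos(2 * pi * seq_len(nseg) / (nseg + 1))) else rep(1, nseg)
  u <- mean(w^2)
  nf <- floor(nseg / 2) + 1
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(seg)[seq_len(nf)]
    p <- (Mod(X)^2) / (nseg^2 * u)
    p[2:(nf - 1)] <- 2 * p[2:(nf - 1)] # one-sided fold
    acc <- acc + p
  }
  list(freqs_hz = (seq_len(nf) - 1) * fs / nseg,
       power = acc / length(starts))
}

# width (Hz) of the contiguous region around the global maximum where the
# (smoothed) power stays >= half the maximum
spectral_whm <- function(freqs, power, smooth_bins = 3) {
  p <- if (smooth_bins > 1)
    stats::filter(power, rep(1 / smooth_bins, smooth_bins), sides = 2) else power
  p[is.na(p)] <- power[is.na(p)]
  p <- as.numeric(p)
  i0 <- which.max(p)
  half <- p[i0] / 2
  lo <- i0; while (lo > 1 && p[lo - 1] >= half) lo <- lo - 1
  hi <- i0; while (hi < length(p) && p[hi + 1] >= half) hi <- hi + 1
  freqs[hi] - freqs[lo]
}

#' Power spectrum of an EEG trace
#'
#' Welch averaged-periodogram estimate (4 s Hann segments, 50\% overlap by
#' default) on [0, fs/2], with the spectral width at mid-height (WHM): the
#' width of the contiguous band around the global maximum where power stays
#' at or above half the maximum, measured on a 3-bin moving-average smoothed
#' spectrum to suppress single-bin spikes.
#'
#' @param trace an [eeg_trace()] of at least one segment length.
#' @param seg_s segment length in seconds.
#' @param overlap fractional segment overlap.
#' @param window \code{"hann"} (default) or \code{"rect"}.
#' @param smooth_bins moving-average width for the WHM measurement.
#' @return An object of class \code{eeg_spectrum}: list(freqs_hz, power,
#'   whm_hz).
#' @export
power_spectrum <- function(trace, seg_s = 4, overlap = 0.5,
                           window = "hann", smooth_bins = 3) {
  stopifnot(inherits(trace, "eeg_trace"))
  ps <- welch_psd(trace$samples, trace$fs_hz, seg_s, overlap, window)
  structure(list(freqs_hz = ps$freqs_hz, power = ps$power,
                 whm_hz = spectral_whm(ps$freqs_hz, ps$power, smooth_bins)),
            class = "eeg_spectrum")
}

#' Locate dominant spectral peaks below a frequency cap
#'
#' Finds local maxima of the (smoothed) power spectrum below \code{max_hz}
#' and returns the \code{n} largest by power, sorted by frequency.
#'
#' @param spectrum an [power_spectrum()] result.
#' @param n number of peaks to return.
#' @param max_hz only peaks strictly below this frequency are considered.
#' @param smooth_bins moving-average width before peak picking.
#' @return Data frame (freq_hz, power), one row per peak, ascending in
#'   frequency.
#' @export
spectral_peaks <- function(spectrum, n = 2, max_hz = 10, smooth_bins = 1) {
  f <- spectrum$freqs_hz; p <- spectrum$power
  if (smooth_bins > 1) {
    ps <- as.numeric(stats::filter(p, rep(1 / smooth_bins, smooth_bins),
                                   sides = 2))
    p <- ifelse(is.na(ps), p, ps)
  }
  k <- which(f < max_hz)
  loc <- k[k > 1 & k < length(p) & p[k] > p[pmax(k - 1, 1)] &
             p[k] >= p[pmin(k + 1, length(p))]]
  loc <- loc[order(p[loc], decreasing = TRUE)]
  loc <- sort(loc[seq_len(min(n, length(loc)))])
  data.frame(freq_hz = f[loc], power = p[loc])
}

#' Amplitude probability distribution of an EEG trace
#'
#' Normalized histogram of sample amplitudes plus the excess kurtosis of the
#' amplitude distribution. Burst-suppression records (a sharp peak at
#' baseline with long high-amplitude wings) show strongly positive excess
#' kurtosis; broadband wake activity is near Gaussian (excess ~ 0).
#'
#' @param trace an [eeg_trace()].
#' @param n_bins number of histogram bins (>= 3).
#' @return An object of class \code{amplitude_distribution}:
#'   list(bin_edges, probability, excess_kurtosis).
#' @export
amplitude_distribution <- function(trace, n_bins = 101) {
  stopifnot(inherits(trace, "eeg_trace"), n_bins >= 3)
  x <- trace$samples
  if (diff(range(x)) == 0) stop("constant trace: zero-width histogram")
  h <- graphics::hist(x, breaks = seq(min(x), max(x), length.out = n_bins + 1),
                      plot = FALSE)
  m2 <- mean((x - mean(x))^2)
  m4 <- mean((x - mean(x))^4)
  structure(list(bin_edges = h$breaks,
                 probability = h$counts / length(x),
                 excess_kurtosis = m4 / m2^2 - 3),
            class = "amplitude_distribution")
}

#' Sliding-FFT spectrogram of an EEG trace
#'
#' Time-frequency representation from a sliding FFT: a \code{window_s}-long
#' window stepped by \code{step_s} (defaults 4 s and 0.5 s), log-amplitude,
#' max-normalized per record for display. The number of time bins is
#' floor((duration - window) / step) + 1.
#'
#' @param trace an [eeg_trace()] of at least one window.
#' @param window_s window length, seconds.
#' @param step_s step size, seconds.
#' @return An object of class \code{eeg_spectrogram}: list(times_s,
#'   freqs_hz, log_amplitude — freq x time matrix, normalized to max 0).
#' @export
eeg_spectrogram <- function(trace, window_s = 4, step_s = 0.5) {
  stopifnot(inherits(trace, "eeg_trace"))
  fs <- trace$fs_hz
  nwin <- round(window_s * fs)
  nstep <- round(step_s * fs)
  x <- trace$samples
  if (length(x) < nwin) stop("trace shorter than one spectrogram window")
  starts <- seq(1, length(x) - nwin + 1, by = nstep)
  nf <- floor(nwin / 2) + 1
  amp <- matrix(0, nf, length(starts))
  w <- 0.5 * (1 - cos(2 * pi * seq_len(nwin) / (nwin + 1)))
  for (i in seq_along(starts)) {
    seg <- x[starts[i]:(starts[i] + nwin - 1)]
    amp[, i] <- Mod(stats::fft((seg - mean(seg)) * w)[seq_len(nf)])
  }
  la <- log10(amp + .Machine$double.eps)
  structure(list(times_s = (starts - 1) / fs + window_s / 2,
                 freqs_hz = (seq_len(nf) - 1) * fs / nwin,
                 log_amplitude = la - max(la)),
            class = "eeg_spectrogram")
}
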