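# Gamma-oscillation analysis: band-pass preprocessing, Welch power spectra
# with 18-50 Hz peak extraction, within-experiment normalized peak power,
# and FFT cross-correlation with millisecond lag between the deep and
# superficial channels.

GAMMA_BAND <- c(18, 50)

#' Preprocess an extracellular signal
#'
#' Mean subtraction followed by a zero-phase band-pass (Butterworth applied
#' forward-backward via `signal::filtfilt`). Corner frequencies default to
#' 8 and 100 Hz.
#'
#' @param x numeric signal.
#' @param fs sampling rate, Hz (> 200).
#' @param low,high corner frequencies, Hz. Defaults 8 and 100.
#' @param order Butterworth design order per band edge (2 gives a 4th-order
#'   band-pass before the forward-backward pass). Default 2.
#' @return Filtered, zero-mean signal.
#' @export
lfp_preprocess <- function(x, fs, low = 8, high = 100, order = 2) {
  if (fs <= 200) stop_ca1("fs must exceed 200 Hz",
                          class = "ca1quant_config_error")
  settle <- ceiling(fs / low)  # one period of the lowest corner
  if (length(x) < 3 * settle) {
    stop_ca1("signal shorter than 3x the filter settling length",
             class = "ca1quant_length_error")
  }
  x <- x - mean(x)
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Welch power spectrum with gamma-band peak
#'
#' Averaged modified periodogram (Hann window, 50% overlap by default,
#' 1-second segments giving 1 Hz resolution). Power is scaled so the bins
#' sum to the signal's mean-square amplitude (Vrms^2); `peak_power_vrms` is
#' the square root of the power in the peak bin. The peak search is
#' restricted to `band` (18-50 Hz).
#'
#' @param x preprocessed signal.
#' @param fs sampling rate, Hz.
#' @param segment_s segment length in seconds. Default 1.
#' @param overlap fractional overlap between segments. Default 0.5.
#' @param band peak-search band, Hz. Default `c(18, 50)`.
#' @return List of class `spectrum_result`: `freqs`, `power` (Vrms^2 per
#'   bin), `peak_freq_Hz`, `peak_power_vrms`, `band`, `df_Hz`.
#' @export
power_spectrum <- function(x, fs, segment_s = 1, overlap = 0.5,
                           band = GAMMA_BAND) {
  nper <- round(segment_s * fs)
  step <- max(1L, round(nper * (1 - overlap)))
  if (length(x) < 2 * nper - step) {
    stop_ca1("signal shorter than two Welch segments",
             class = "ca1quant_length_error")
  }
  starts <- seq(1L, length(x) - nper + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nper) / (nper + 1))  # Hann
  norm <- sum(w^2)
  acc <- numeric(nper)
  for (s in starts) {
    seg <- x[s:(s + nper - 1L)] * w
    acc <- acc + Mod(stats::fft(seg))^2 / norm
  }
  p_full <- acc / length(starts)
  nf <- floor(nper / 2) + 1L
  power <- p_full[seq_len(nf)] / nper
  if (nf > 1L) {
    last <- if (nper %% 2 == 0) nf - 1L else nf
    power[2:last] <- power[2:last] * 2  # fold negative frequencies
  }
  freqs <- (seq_len(nf) - 1L) * fs / nper
  in_band <- which(freqs >= band[1] & freqs <= band[2])
  if (!length(in_band)) stop_ca1("no frequency bins inside the band",
                                 class = "ca1quant_config_error")
  pk <- in_band[which.max(power[in_band])]
  structure(list(freqs = freqs, power = power,
                 peak_freq_Hz = freqs[pk],
                 peak_power_vrms = sqrt(power[pk]),
                 band = band, df_Hz = fs / nper),
            class = "spectrum_result")
}

#' Normalized peak power between paired recordings
#'
#' Locates the gamma-band peak in the pre (baseline) spectrum and reads the
#' same frequency bin in the post spectrum; returns the ratio of Vrms
#' values (1 = no change). Both spectra must share a frequency grid, as
#' within one experiment.
#'
#' @param pre,post `spectrum_result` objects from [power_spectrum()].
#' @return Dimensionless post/pre Vrms ratio at the baseline peak frequency.
#' @export
normalized_peak_power <- function(pre, post) {
  stopifnot(inherits(pre, "spectrum_result"),
            inherits(post, "spectrum_result"))
  if (length(pre$freqs) != length(post$freqs) ||
      any(pre$freqs != post$freqs)) {
    stop_ca1("pre and post spectra are not on the same frequency grid",
             class = "ca1quant_pairing_error")
  }
  i <- which(pre$freqs == pre$peak_freq_Hz)
  sqrt(post$power[i]) / sqrt(pre$power[i])
}

# Linear cross-correlation c(k) = sum_t x[t] y[t+k] via zero-padded FFTs;
# positive k means y is a delayed copy of x (the deep channel leads).
xcorr_core <- function(x, y, max_lag) {
  n <- length(x)
  nfft <- 2^ceiling(log2(2 * n - 1))
  X <- stats::fft(c(x, numeric(nfft - n)))
  Y <- stats::fft(c(y, numeric(nfft - n)))
  c_full <- Re(stats::fft(Conj(X) * Y, inverse = TRUE)) / nfft
  k <- -max_lag:max_lag
  c_full[ifelse(k >= 0, k + 1L, nfft + k + 1L)]
}

#' FFT cross-correlation between deep and superficial channels
#'
#' Cross-correlation computed in the frequency domain with zero-padding
#' (linear, not circular, correlation), optionally averaged over
#' consecutive windows, restricted to `|lag| <= max_lag_ms`. The maximum of
#' the real part is the correlation summary value; the signed lag at that
#' maximum uses the convention that a positive lag means the deep channel
#' leads the superficial channel. Peak ties resolve to the smallest `|lag|`
#' (and to the positive lag on an exact +/- tie).
#'
#' @param x deep-channel signal (preprocessed).
#' @param y superficial-channel signal, same length.
#' @param fs sampling rate, Hz.
#' @param max_lag_ms lag window. Default 25.
#' @param window_s analysis-window length in seconds over which
#'   correlation curves are averaged; `NULL` uses the whole record as one
#'   window. Default `NULL`.
#' @param circular use strict circular correlation (no zero-padding)
#'   instead of linear. Default `FALSE`.
#' @return List of class `xcorr_result`: `lags_ms`, `values`, `max_value`,
#'   `lag_at_max_ms`, `window_s`.
#' @export
xcorr_fft <- function(x, y, fs, max_lag_ms = 25, window_s = NULL,
                      circular = FALSE) {
  if (length(x) != length(y)) {
    stop_ca1("channel lengths differ", class = "ca1quant_shape_error")
  }
  max_lag <- round(max_lag_ms / 1000 * fs)
  if (max_lag >= length(x)) stop_ca1("max lag exceeds signal length",
                                     class = "ca1quant_shape_error")
  wlen <- if (is.null(window_s)) length(x) else round(window_s * fs)
  starts <- seq(1L, length(x) - wlen + 1L, by = wlen)
  vals <- numeric(2 * max_lag + 1)
  for (s in starts) {
    i <- s:(s + wlen - 1L)
    vals <- vals + if (circular) {
      xc <- Re(stats::fft(Conj(stats::fft(x[i])) * stats::fft(y[i]),
                          inverse = TRUE)) / wlen
      k <- -max_lag:max_lag
      xc[ifelse(k >= 0, k + 1L, wlen + k + 1L)]
    } else {
      xcorr_core(x[i], y[i], max_lag)
    }
  }
  vals <- vals / length(starts)
  lags_ms <- (-max_lag:max_lag) / fs * 1000
  peak <- max(vals)
  at_peak <- which(vals >= peak - .Machine$double.eps * abs(peak))
  best <- at_peak[order(abs(lags_ms[at_peak]), -lags_ms[at_peak])][1]
  structure(list(lags_ms = lags_ms, values = vals, max_value = peak,
                 lag_at_max_ms = lags_ms[best],
                 window_s = if (is.null(window_s)) NA_real_ else window_s),
            class = "xcorr_result")
}

#' Full two-channel gamma analysis for one experiment
#'
#' Preprocesses both channels, computes per-channel spectra, and the
#' deep-vs-superficial cross-correlation averaged over 1-second windows.
#'
#' @param rec an `lfp_recording` (see [gen_lfp()]) or a list with
#'   `channel_deep`, `channel_superficial`, `sampling_rate`.
#' @param max_lag_ms lag window for the cross-correlation. Default 25.
#' @param window_s averaging-window length, seconds. Default 1.
#' @return List: `spectrum_deep`, `spectrum_superficial`, `xcorr`,
#'   `peak_freq_Hz` (deep channel).
#' @export
analyze_lfp <- function(rec, max_lag_ms = 25, window_s = 1) {
  fs <- rec$sampling_rate
  d <- lfp_preprocess(rec$channel_deep, fs)
  s <- lfp_preprocess(rec$channel_superficial, fs)
  spd <- power_spectrum(d, fs)
  sps <- power_spectrum(s, fs)
  xc <- xcorr_fft(d, s, fs, max_lag_ms = max_lag_ms, window_s = window_s)
  list(spectrum_deep = spd, spectrum_superficial = sps, xcorr = xc,
       peak_freq_Hz = spd$peak_freq_Hz)
}
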