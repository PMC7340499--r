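# Intrinsic-property extraction from current-clamp sweeps, recording QC,
# and synaptic-pharmacology outcomes (wash-in percent of baseline, I/E
# ratio with monosynaptic subtraction).

#' Construct an electrophysiology sweep
#'
#' @param samples numeric vector, mV (current clamp) or pA (voltage clamp).
#' @param sampling_rate Hz (> 0).
#' @param stim_onset,stim_offset stimulus window, seconds from sweep start.
#' @param stim_amplitude step amplitude (pA in current clamp).
#' @param holding bias level applied outside the step (pA). Default 0.
#' @param sweep_id optional identifier.
#' @return An object of class `ephys_sweep`.
#' @export
ephys_sweep <- function(samples, sampling_rate, stim_onset, stim_offset,
                  stim_amplitude, holding = 0, sweep_id = NULL) {
  if (sampling_rate <= 0) stop_ca1("sampling_rate must be > 0",
                                   class = "ca1quant_config_error")
  if (!all(is.finite(samples))) stop_ca1("non-finite samples",
                                         class = "ca1quant_data_error")
  dur <- length(samples) / sampling_rate
  if (stim_onset < 0 || stim_offset > dur || stim_offset <= stim_onset) {
    stop_ca1("stimulus window [", stim_onset, ", ", stim_offset,
             "] s outside the ", round(dur, 4), " s record",
             class = "ca1quant_config_error")
  }
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 stim_onset = stim_onset, stim_offset = stim_offset,
                 stim_amplitude = stim_amplitude, holding = holding,
                 sweep_id = sweep_id),
            class = "ephys_sweep")
}

sweep_idx <- function(sw, t0, t1) {
  i0 <- max(1L, floor(t0 * sw$sampling_rate) + 1L)
  i1 <- min(length(sw$samples), ceiling(t1 * sw$sampling_rate))
  if (i1 < i0) integer(0) else i0:i1
}

baseline_mean <- function(sw) mean(sw$samples[sweep_idx(sw, 0, sw$stim_onset)])

#' Resting membrane potential
#'
#' Mean of the pre-stimulus baseline segment, which must be at least
#' `min_baseline_s` long and carry zero injected current.
#'
#' @param sw an [ephys_sweep()].
#' @param min_baseline_s minimum baseline duration (s). Default 0.1.
#' @return RMP in mV.
#' @export
resting_membrane_potential <- function(sw, min_baseline_s = 0.1) {
  stopifnot(inherits(sw, "ephys_sweep"))
  if (sw$stim_onset < min_baseline_s) {
    stop_ca1("pre-stimulus baseline shorter than ", min_baseline_s, " s",
             class = "ca1quant_precondition_error")
  }
  if (sw$holding != 0) {
    stop_ca1("baseline segment carries non-zero holding current",
             class = "ca1quant_precondition_error")
  }
  baseline_mean(sw)
}

#' Sag index of a hyperpolarizing step response
#'
#' `sag = dV_ss / dV_peak`, where `dV_peak = baseline - min(V)` within the
#' step and `dV_ss = baseline - mean(V)` over the last `ss_frac` of the
#' step. Values close to 1 correspond to less sag; a pure RC response
#' (no sag) gives exactly 1 up to steady-state estimation error.
#'
#' @param sw an [ephys_sweep()] with a hyperpolarizing (`stim_amplitude < 0`) step.
#' @param ss_frac fraction of the step treated as steady state. Default 0.2.
#' @return Dimensionless sag index in `(0, 1]`.
#' @export
sag_index <- function(sw, ss_frac = 0.2) {
  stopifnot(inherits(sw, "ephys_sweep"))
  if (sw$stim_amplitude >= 0) {
    stop_ca1("sag index requires a hyperpolarizing step",
             class = "ca1quant_polarity_error")
  }
  bl <- baseline_mean(sw)
  step <- sweep_idx(sw, sw$stim_onset, sw$stim_offset)
  v <- sw$samples[step]
  dv_peak <- bl - min(v)
  t_ss <- sw$stim_offset - ss_frac * (sw$stim_offset - sw$stim_onset)
  dv_ss <- bl - mean(sw$samples[sweep_idx(sw, t_ss, sw$stim_offset)])
  if (dv_peak <= 0) return(1.0)
  min(dv_ss / dv_peak, 1.0)
}

#' Input resistance from hyperpolarizing step(s)
#'
#' Steady-state voltage deflection regressed on injected current through
#' the origin (a single sweep reduces to `dV/dI`). Units: mV over pA gives
#' megaohms after the factor 1000.
#'
#' @param sweeps an [ephys_sweep()] or list of sweeps with known step amplitudes.
#' @param ss_frac steady-state fraction of the step. Default 0.2.
#' @return Input resistance in MOhm.
#' @export
input_resistance <- function(sweeps, ss_frac = 0.2) {
  if (inherits(sweeps, "ephys_sweep")) sweeps <- list(sweeps)
  di <- vapply(sweeps, function(s) s$stim_amplitude, numeric(1))
  if (any(di == 0)) stop_ca1("zero step amplitude",
                             class = "ca1quant_division_error")
  dv <- vapply(sweeps, function(s) {
    t_ss <- s$stim_offset - ss_frac * (s$stim_offset - s$stim_onset)
    mean(s$samples[sweep_idx(s, t_ss, s$stim_offset)]) - baseline_mean(s)
  }, numeric(1))
  1000 * sum(dv * di) / sum(di * di)  # mV/pA -> MOhm
}

#' Spike-train features at twice rheobase
#'
#' Spikes are taken as local maxima above `peak_min_mV` separated by at
#' least 1 ms. Per spike, threshold is the membrane potential at the first
#' upward crossing of `dV/dt >= dvdt_thresh` before the peak; the first
#' spike's threshold, amplitude (peak - threshold) and AHP (threshold minus
#' the minimum within `ahp_window_ms` after the peak, reported as a
#' positive magnitude) are returned. The adaptation ratio is the last
#' inter-spike interval over the first; firing frequency is the spike count
#' divided by the step duration.
#'
#' @param sw an [ephys_sweep()] at 2x rheobase.
#' @param dvdt_thresh threshold-detection slope, mV/ms. Default 20.
#' @param ahp_window_ms AHP search window after the peak. Default 20.
#' @param peak_min_mV minimum peak height for spike detection. Default -10.
#' @return List: `n_spikes`, `spike_threshold_mV`, `spike_amplitude_mV`,
#'   `ahp_mV`, `adaptation_ratio`, `f_2x_Hz`, `spike_times_s`. Features are
#'   `NA` when fewer spikes than they require are present.
#' @export
spike_train_features <- function(sw, dvdt_thresh = 20, ahp_window_ms = 20,
                                 peak_min_mV = -10) {
  stopifnot(inherits(sw, "ephys_sweep"))
  fs <- sw$sampling_rate
  v <- sw$samples
  step <- sweep_idx(sw, sw$stim_onset, sw$stim_offset)
  dur <- sw$stim_offset - sw$stim_onset
  refr <- max(1L, round(fs / 1000))  # 1 ms
  # local maxima above peak_min_mV within the step, 1 ms separation
  cand <- step[which(v[step] > peak_min_mV)]
  cand <- cand[cand > 1 & cand < length(v)]
  cand <- cand[v[cand] >= v[cand - 1] & v[cand] > v[cand + 1]]
  peaks <- integer(0)
  for (i in cand) {
    if (!length(peaks) || i - peaks[length(peaks)] > refr) {
      peaks <- c(peaks, i)
    } else if (v[i] > v[peaks[length(peaks)]]) {
      peaks[length(peaks)] <- i
    }
  }
  n <- length(peaks)
  out <- list(n_spikes = n, spike_threshold_mV = NA_real_,
              spike_amplitude_mV = NA_real_, ahp_mV = NA_real_,
              adaptation_ratio = NA_real_, f_2x_Hz = n / dur,
              spike_times_s = (peaks - 1) / fs)
  if (n < 1L) return(out)
  dvdt <- c(0, diff(v)) * fs / 1000  # mV/ms
  thr_idx <- function(pk) {
    lo <- if (pk == peaks[1]) step[1] else peaks[which(peaks == pk) - 1L]
    seg <- lo:pk
    up <- seg[dvdt[seg] >= dvdt_thresh & c(-Inf, dvdt[seg[-length(seg)]]) <
                dvdt_thresh]
    if (!length(up)) seg[which(dvdt[seg] >= dvdt_thresh)[1]] else up[1]
  }
  ti <- thr_idx(peaks[1])
  if (!is.na(ti)) {
    out$spike_threshold_mV <- v[ti]
    out$spike_amplitude_mV <- v[peaks[1]] - v[ti]
    w <- peaks[1]:min(length(v), peaks[1] + round(ahp_window_ms / 1000 * fs))
    out$ahp_mV <- v[ti] - min(v[w])
  }
  if (n >= 2L) {
    isi <- diff(peaks) / fs
    out$adaptation_ratio <- isi[length(isi)] / isi[1]
  }
  out
}

#' Series-resistance stability QC
#'
#' Percent change over the recording is `(max - min)/min * 100`; the cell
#' fails when it exceeds `max_change_pct` (cells varying by more than 30%
#' are conventionally excluded).
#'
#' @param sr_values series-resistance measurements (MOhm), >= 2 values.
#' @param max_change_pct failure threshold. Default 30.
#' @return List: `pass`, `percent_change`.
#' @export
series_resistance_qc <- function(sr_values, max_change_pct = 30) {
  if (length(sr_values) < 2L) {
    stop_ca1("need >= 2 series-resistance measurements",
             class = "ca1quant_precondition_error")
  }
  if (any(!is.finite(sr_values)) || any(sr_values <= 0)) {
    stop_ca1("series resistance must be positive and finite",
             class = "ca1quant_data_error")
  }
  pct <- (max(sr_values) - min(sr_values)) / min(sr_values) * 100
  list(pass = pct <= max_change_pct, percent_change = pct)
}

#' Construct a wash-in amplitude series
#'
#' @param event_times_min event times in minutes relative to drug onset
#'   (negative = baseline).
#' @param amplitudes_pA evoked-event amplitude magnitudes (>= 0).
#' @param baseline_window minutes, default `c(-5, 0)`.
#' @param assay_window minutes after onset, default `c(10, 12)` (inclusive).
#' @param drug_label free-form drug tag.
#' @return An object of class `washin_series`.
#' @export
washin_series <- function(event_times_min, amplitudes_pA,
                          baseline_window = c(-5, 0),
                          assay_window = c(10, 12), drug_label = "") {
  stopifnot(length(event_times_min) == length(amplitudes_pA))
  if (any(amplitudes_pA < 0)) stop_ca1("amplitudes must be magnitudes >= 0",
                                       class = "ca1quant_data_error")
  if (baseline_window[2] > 0) stop_ca1("baseline window must precede onset",
                                       class = "ca1quant_config_error")
  structure(list(event_times_min = event_times_min,
                 amplitudes_pA = amplitudes_pA,
                 baseline_window = baseline_window,
                 assay_window = assay_window, drug_label = drug_label),
            class = "washin_series")
}

#' Percent of baseline amplitude after drug wash-in
#'
#' `100 * mean(amplitudes in the assay window) / mean(baseline amplitudes)`;
#' both windows are inclusive of their endpoints and must contain at least
#' `min_events` events.
#'
#' @param series a [washin_series()].
#' @param min_events minimum events per window. Default 3.
#' @return Percent of baseline (100 = no effect).
#' @export
washin_percent_of_baseline <- function(series, min_events = 3L) {
  stopifnot(inherits(series, "washin_series"))
  t <- series$event_times_min
  in_bl <- t >= series$baseline_window[1] & t <= series$baseline_window[2]
  in_as <- t >= series$assay_window[1] & t <= series$assay_window[2]
  if (sum(in_bl) < min_events || sum(in_as) < min_events) {
    stop_ca1("need >= ", min_events, " events in baseline and assay windows",
             class = "ca1quant_windowing_error")
  }
  100 * mean(series$amplitudes_pA[in_as]) / mean(series$amplitudes_pA[in_bl])
}

#' Wash-in inclusion rule
#'
#' Experiments whose evoked events were not reduced by at least
#' `min_reduction_pct` are excluded: include iff percent-of-baseline
#' `<= 100 - min_reduction_pct` (the boundary itself is included).
#'
#' @param series a [washin_series()].
#' @param min_reduction_pct default 30.
#' @return List: `include`, `percent_of_baseline`.
#' @export
washin_inclusion <- function(series, min_reduction_pct = 30) {
  pct <- washin_percent_of_baseline(series)
  list(include = pct <= 100 - min_reduction_pct, percent_of_baseline = pct)
}

#' Feedforward inhibition:excitation ratio
#'
#' The disynaptic IPSC is `ipsc_total - ipsc_mono` when the monosynaptic
#' component was measured (glutamate-blockade experiments), or `ipsc_total`
#' itself when it was not (the pooled CA3-stimulation case);
#' `ie_ratio = disynaptic / epsc_amp`.
#'
#' @param epsc_amp_pA monosynaptic EPSC amplitude at -70 mV (> 0).
#' @param ipsc_total_pA total IPSC amplitude at +10 mV.
#' @param ipsc_mono_pA monosynaptic IPSC component, or `NULL`.
#' @return List of class `feedforward_result`: the three amplitudes plus
#'   `ipsc_disynaptic_pA` and `ie_ratio`.
#' @export
ie_ratio <- function(epsc_amp_pA, ipsc_total_pA, ipsc_mono_pA = NULL) {
  if (epsc_amp_pA <= 0) stop_ca1("epsc_amp must be > 0",
                                 class = "ca1quant_division_error")
  if (ipsc_total_pA < 0 || (!is.null(ipsc_mono_pA) && ipsc_mono_pA < 0)) {
    stop_ca1("amplitudes must be >= 0", class = "ca1quant_data_error")
  }
  if (!is.null(ipsc_mono_pA) && ipsc_mono_pA > ipsc_total_pA) {
    stop_ca1("monosynaptic IPSC exceeds total IPSC",
             class = "ca1quant_consistency_error")
  }
  dis <- if (is.null(ipsc_mono_pA)) ipsc_total_pA else
    ipsc_total_pA - ipsc_mono_pA
  structure(list(epsc_amp_pA = epsc_amp_pA, ipsc_total_pA = ipsc_total_pA,
                 ipsc_mono_pA = ipsc_mono_pA, ipsc_disynaptic_pA = dis,
                 ie_ratio = dis / epsc_amp_pA),
            class = "feedforward_result")
}
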