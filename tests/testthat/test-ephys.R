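# Intrinsic-property extraction, QC rules, wash-in and I/E outcomes.

flat_sweep <- function(level = -63, fs = 10000, dur = 1, onset = 0.3,
                       offset = 0.8, amp = -50) {
  ephys_sweep(rep(level, fs * dur), fs, onset, offset, amp)
}

test_that("resting membrane potential is the baseline mean", {
  expect_equal(resting_membrane_potential(flat_sweep(-63)), -63)
  set.seed(1)
  fs <- 10000
  v <- c(rnorm(0.2 * fs, -60, 0.5), rep(-66, 0.6 * fs))
  sw <- ephys_sweep(v, fs, 0.2, 0.7, -50)
  expect_equal(resting_membrane_potential(sw), -60, tolerance = 0.1)
  # baseline shorter than the minimum window
  sw2 <- ephys_sweep(rep(-60, fs), fs, 0.05, 0.5, -50)
  expect_error(resting_membrane_potential(sw2),
               class = "ca1quant_precondition_error")
})

test_that("the sag index follows its closed form and is monotone in sag
           depth", {
  fs <- 10000
  mk <- function(peak, steady, bl = -65) {
    tstep <- seq(0, 0.5 - 1 / fs, by = 1 / fs)
    v <- c(rep(bl, 0.2 * fs),
           steady + (peak - steady) * exp(-tstep / 0.02),
           rep(bl, 0.1 * fs))
    ephys_sweep(v, fs, 0.2, 0.7, -100)
  }
  expect_equal(sag_index(mk(-80, -75)), 10 / 15, tolerance = 1e-3)
  expect_lt(sag_index(mk(-85, -75)), sag_index(mk(-80, -75)))
  expect_equal(sag_index(mk(-85, -75)), 0.5, tolerance = 1e-3)

  # pure RC response (monotone approach, no sag) scores 1
  rc <- mk(-75, -75)
  expect_equal(sag_index(rc), 1.0, tolerance = 1e-9)
  expect_error(sag_index(flat_sweep(amp = 100)),
               class = "ca1quant_polarity_error")
})

test_that("input resistance recovers Ohm's law and the RC model's ground
           truth", {
  fs <- 10000
  v <- c(rep(-65, 0.2 * fs), rep(-71, 0.5 * fs), rep(-65, 0.1 * fs))
  sw <- ephys_sweep(v, fs, 0.2, 0.7, -50)   # -6 mV for -50 pA
  expect_equal(input_resistance(sw), 120)
  # doubling the step doubles the deflection: same Rin from the joint fit
  v2 <- c(rep(-65, 0.2 * fs), rep(-77, 0.5 * fs), rep(-65, 0.1 * fs))
  sw2 <- ephys_sweep(v2, fs, 0.2, 0.7, -100)
  expect_equal(input_resistance(list(sw, sw2)), 120)
  expect_error(input_resistance(flat_sweep(amp = 0)),
               class = "ca1quant_division_error")

  mdl <- rc_sag_model(rin_MOhm = 150, sag_true = 0.667)
  expect_equal(input_resistance(mdl$sweep), mdl$true_rin,
               tolerance = 1e-6)
})

test_that("spike-train features match the constructed waveform", {
  # 10 uniformly spaced spikes: adaptation ratio exactly 1
  st <- spike_train_sweep(seq(0.15, 0.15 + 9 * 0.04, by = 0.04))
  f <- spike_train_features(st)
  expect_equal(f$n_spikes, 10L)
  expect_equal(f$adaptation_ratio, 1.0, tolerance = 1e-9)
  expect_equal(f$spike_threshold_mV, -45, tolerance = 1.5)
  expect_equal(f$spike_amplitude_mV, 80, tolerance = 2)
  expect_equal(f$ahp_mV, 15, tolerance = 2)

  # 15 spikes on a 500 ms step: 30 Hz
  st2 <- spike_train_sweep(seq(0.12, 0.12 + 14 * 0.03, by = 0.03))
  f2 <- spike_train_features(st2)
  expect_equal(f2$f_2x_Hz, 30)

  # spike counts agree with an independent local-maxima count
  for (s in 1:20) {
    set.seed(s)
    n_sp <- sample(2:12, 1)
    times <- sort(runif(n_sp, 0.12, 0.58))
    while (any(diff(times) < 0.012)) times <- sort(runif(n_sp, 0.12, 0.58))
    sw <- spike_train_sweep(times)
    expect_equal(spike_train_features(sw)$n_spikes, n_sp)
  }

  # sub-threshold sweep: undefined features flagged
  f0 <- spike_train_features(flat_sweep(-70, amp = 200))
  expect_equal(f0$n_spikes, 0L)
  expect_true(is.na(f0$spike_amplitude_mV))
})

test_that("series-resistance QC applies the 30% rule", {
  expect_equal(series_resistance_qc(c(20, 24)),
               list(pass = TRUE, percent_change = 20))
  qc <- series_resistance_qc(c(20, 26.1))
  expect_false(qc$pass)
  expect_equal(qc$percent_change, 30.5)
  expect_true(series_resistance_qc(rep(18, 5))$pass)
  expect_error(series_resistance_qc(c(-1, 20)),
               class = "ca1quant_data_error")
  expect_error(series_resistance_qc(20),
               class = "ca1quant_precondition_error")
})

test_that("wash-in percentage, scale invariance and the inclusion rule
           behave as documented", {
  mk <- function(base_amp, assay_amp) {
    t <- seq(-4, 12.4, by = 0.2)
    amps <- ifelse(t <= 0, base_amp, assay_amp)
    washin_series(t, amps)
  }
  expect_equal(washin_percent_of_baseline(mk(200, 200)), 100)
  expect_equal(washin_percent_of_baseline(mk(200, 105)), 52.5)
  # scale invariance
  s1 <- mk(200, 105); s2 <- mk(600, 315)
  expect_equal(washin_percent_of_baseline(s1),
               washin_percent_of_baseline(s2))
  # inclusion boundary: reduced by exactly 30% still included
  expect_true(washin_inclusion(mk(200, 140))$include)   # 70%
  expect_true(washin_inclusion(mk(200, 138))$include)   # 69%
  expect_false(washin_inclusion(mk(200, 170))$include)  # 85%
  # empty assay window
  short <- washin_series(seq(-4, 5, by = 0.2),
                         rep(100, length(seq(-4, 5, by = 0.2))))
  expect_error(washin_percent_of_baseline(short),
               class = "ca1quant_windowing_error")
})

test_that("the wash-in estimator recovers the generator's drug factor
           within its sampling error", {
  # 10% event noise, ~11 events in the assay window, ~26 at baseline
  est <- vapply(1:30, function(s)
    washin_percent_of_baseline(gen_washin(drug_factor = 0.6, seed = s)),
    numeric(1))
  se_analytic <- 60 * 0.1 * sqrt(1 / 11 + 1 / 26)
  expect_lt(abs(mean(est) - 60), 2 * se_analytic / sqrt(30) + 0.5)
  expect_lt(sd(est), 3 * se_analytic)
})

test_that("I/E ratios subtract the monosynaptic component and scale
           correctly", {
  expect_equal(ie_ratio(100, 400, 85)$ie_ratio, 3.15)
  expect_equal(ie_ratio(100, 400, 400)$ie_ratio, 0)
  expect_equal(ie_ratio(100, 500)$ie_ratio, 5.0)
  # invariance to a common rescaling
  expect_equal(ie_ratio(100, 400, 85)$ie_ratio,
               ie_ratio(250, 1000, 212.5)$ie_ratio)
  expect_error(ie_ratio(0, 400, 85), class = "ca1quant_division_error")
  expect_error(ie_ratio(100, 300, 400),
               class = "ca1quant_consistency_error")
})
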