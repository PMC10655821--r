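test_that("baseline noise estimation follows the first-second rule", {
  fs <- 20000
  rec0 <- voltage_recording(rep(0, fs * 2), fs)
  expect_equal(estimate_noise_sd(rec0), 0)
  set.seed(3)
  rec <- voltage_recording(rnorm(fs * 2, 0, 8), fs)
  expect_true(estimate_noise_sd(rec) > 7.8 && estimate_noise_sd(rec) < 8.2)
  ## multiplier 5 on 4 uV noise implies a 20 uV threshold
  set.seed(3)
  rec4 <- voltage_recording(rnorm(fs * 2, 0, 4), fs)
  tr <- detect_spikes(rec4)
  expect_equal(tr$threshold_used, 5 * estimate_noise_sd(rec4))
  expect_lt(abs(tr$threshold_used - 20), 1)
  expect_error(estimate_noise_sd(voltage_recording(rnorm(100), fs)),
               "baseline")
})

test_that("rendered templates have the stated shape and clean baseline", {
  fs <- 20000
  ## noiseless single spike: minimum is -amplitude at the spike time
  tr <- spike_train(2, 60, duration = 4)
  rec <- render_voltage(tr, noise_sd = 0, sampling_rate = fs)
  expect_equal(min(rec$samples), -60)
  expect_equal((which.min(rec$samples) - 1) / fs, 2, tolerance = 1e-4)
  ## empty train: trace SD matches the requested noise SD within 2%
  tr0 <- spike_train(numeric(0), numeric(0), duration = 60)
  rec0 <- render_voltage(tr0, noise_sd = 8, seed = 3)
  expect_lt(abs(sd(rec0$samples) - 8) / 8, 0.02)
  ## 100 spikes at 60 uV in 8 uV noise all exceed the 40 uV threshold
  set.seed(6)
  times <- sort(runif(100, 1.5, 58))
  times <- times[c(TRUE, diff(times) > 0.01)]
  trn <- spike_train(times, rep(60, length(times)), duration = 60)
  rec <- render_voltage(trn, noise_sd = 8, seed = 8)
  idx <- round(times * fs) + 1
  peaks <- vapply(idx, function(i) min(rec$samples[(i - 10):(i + 10)]),
                  numeric(1))
  expect_true(all(peaks < -40))
  ## simulator keeps the first second spike-free
  p <- test_profile(tonic = 10, burst_rate = 6, burst_duration = 0.3,
                    isi = 0.01)
  sim <- simulate_spike_trains(p, plate_spec(n_wells = 2, duration = 60),
                               seed = 5, divs = 10)
  expect_true(all(vapply(sim$trains, function(tr) {
    !length(tr$times) || min(tr$times) >= 1
  }, logical(1))))
  expect_error(render_voltage(spike_train(1, -5, duration = 2)), "positive")
})

test_that("threshold crossing detection recovers injected spikes", {
  fs <- 20000
  expect_length(detect_spikes(voltage_recording(rep(0, fs * 2), fs))$times, 0)
  set.seed(5)
  times <- seq(1.5, 10.5, by = 1)
  tr <- spike_train(times, rep(60, 10), duration = 12)
  rec <- render_voltage(tr, noise_sd = 8, seed = 5)
  det <- detect_spikes(rec)
  expect_length(det$times, 10)
  expect_true(all(abs(det$times - times) <= 0.001))
  expect_true(all(det$amplitudes > 40))
})

test_that("crossings within the dead time are absorbed into one spike", {
  fs <- 20000
  x <- rnorm(fs * 2, 0, 1)          # 1 uV noise -> threshold 5 uV
  ## two sub-threshold excursions 1 ms apart
  x[fs + (1:5)] <- -30
  x[fs + 20 + (1:5)] <- -40
  det <- detect_spikes(voltage_recording(x, fs))
  expect_length(det$times, 1)
  expect_equal(det$amplitudes, 40, tolerance = 1e-6)
})

test_that("noiseless renderings are recovered exactly (within one sample)", {
  fs <- 20000
  set.seed(9)
  for (rep in 1:5) {
    n <- sample(5:40, 1)
    times <- sort(1.2 + cumsum(runif(n, 0.004, 0.3)))
    tr <- spike_train(times, rnorm_trunc(n, 60, 10, 25), duration = max(times) + 1)
    rec <- render_voltage(tr, noise_sd = 0.01, seed = rep)
    det <- detect_spikes(rec)
    expect_length(det$times, n)
    expect_true(all(abs(det$times - times) <= 1 / fs + 1e-9))
  }
})

test_that("false-positive rate on pure noise is below 0.1 spikes/s", {
  set.seed(13)
  rec <- voltage_recording(rnorm(20000 * 60, 0, 8), 20000)
  det <- detect_spikes(rec)
  expect_lt(length(det$times) / 60, 0.1)
})

test_that("detected rate is monotone non-increasing in the noise multiplier", {
  set.seed(21)
  times <- sort(runif(50, 1.2, 28))
  times <- times[c(TRUE, diff(times) > 0.005)]
  tr <- spike_train(times, rnorm_trunc(length(times), 45, 15, 20),
                    duration = 30)
  rec <- render_voltage(tr, noise_sd = 8, seed = 2)
  counts <- vapply(c(3, 4, 5, 6, 7), function(m) {
    length(detect_spikes(rec, detection_params(noise_multiplier = m))$times)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("electrode and well activity rules follow the 10 spikes/min & 20 uV criteria", {
  mk <- function(n, amp) spike_train(seq_len(n) / n * 59, rep(amp, n),
                                     duration = 60)
  expect_false(electrode_is_active(mk(9, 60)))    # rate below 10/min
  expect_true(electrode_is_active(mk(10, 25)))    # both criteria met
  expect_false(electrode_is_active(mk(50, 15)))   # amplitude below 20 uV
  empty <- spike_train(numeric(0), numeric(0), duration = 60)
  expect_false(well_is_active(rep(list(empty), 12)))
  expect_true(well_is_active(c(list(mk(20, 60)), rep(list(empty), 11))))
  expect_true(well_is_active(rep(list(mk(20, 60)), 12)))
})
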