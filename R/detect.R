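#' Voltage recording container
#'
#' @param samples voltage samples in microvolts.
#' @param sampling_rate samples per second (> 0).
#' @param well,electrode,div,genotype,batch recording metadata.
#' @export
voltage_recording <- function(samples, sampling_rate, well = 1L,
                              electrode = 1L, div = NA,
                              genotype = NA_character_,
                              batch = NA_character_) {
  stop_if_not(sampling_rate > 0, "sampling_rate must be positive")
  structure(list(samples = as.numeric(samples), sampling_rate = sampling_rate,
                 well = well, electrode = electrode, div = div,
                 genotype = genotype, batch = batch),
            class = "voltage_recording")
}

#' @export
print.voltage_recording <- function(x, ...) {
  cat(sprintf("<voltage_recording> well %s el %s div %s: %.1f s @ %g Hz\n",
              x$well, x$electrode, x$div,
              length(x$samples) / x$sampling_rate, x$sampling_rate))
  invisible(x)
}

#' Spike detection parameters
#'
#' The adaptive threshold is `noise_multiplier` times the standard deviation
#' of the baseline noise, estimated from the first `baseline_window` seconds
#' of each electrode's trace. Rates are computed in `rate_bin`-second bins.
#'
#' @param noise_multiplier threshold in units of baseline noise SD.
#' @param baseline_window seconds of trace used for the noise estimate.
#' @param dead_time refractory window in seconds: crossings within this window
#'   of a previous crossing are absorbed into the same spike.
#' @param polarity `"negative"` detects negative-going crossings only
#'   (extracellular spikes are negative-leading); `"both"` also detects
#'   positive crossings.
#' @param rate_bin bin width in seconds for rate computation.
#' @param robust use a median/MAD noise estimate instead of the sample SD
#'   (for spike-contaminated baselines).
#' @export
detection_params <- function(noise_multiplier = 5, baseline_window = 1,
                             dead_time = 0.002,
                             polarity = c("negative", "both"),
                             rate_bin = 1, robust = FALSE) {
  stop_if_not(noise_multiplier > 0, "noise_multiplier must be positive")
  stop_if_not(dead_time > 0, "dead_time must be positive")
  structure(list(noise_multiplier = noise_multiplier,
                 baseline_window = baseline_window, dead_time = dead_time,
                 polarity = match.arg(polarity), rate_bin = rate_bin,
                 robust = robust),
            class = "detection_params")
}

#' Baseline noise standard deviation
#'
#' Sample SD (or, with `robust = TRUE`, 1.4826 x MAD) of the first
#' `baseline_window` seconds of the trace.
#'
#' @param rec a [voltage_recording()].
#' @param params a [detection_params()].
#' @return Noise SD in microvolts.
#' @export
estimate_noise_sd <- function(rec, params = detection_params()) {
  n_base <- round(params$baseline_window * rec$sampling_rate)
  stop_if_not(length(rec$samples) >= n_base,
              "trace shorter than the baseline window")
  x <- rec$samples[seq_len(n_base)]
  if (params$robust) stats::mad(x) else stats::sd(x)
}

## crossings of a (signed) threshold in one direction, with dead-time
## absorption and extremum localization
crossings_one_sign <- function(x, thr, dead_samples, negative) {
  n <- length(x)
  idx <- if (negative) which(x[-1] <= thr & x[-n] > thr) + 1L
         else which(x[-1] >= thr & x[-n] < thr) + 1L
  if (!length(idx)) return(NULL)
  keep_t <- numeric(0); keep_a <- numeric(0)
  last <- -Inf
  for (i in idx) {
    if (i - last < dead_samples) next
    last <- i
    win <- i:min(i + dead_samples, n)
    ext <- if (negative) win[which.min(x[win])] else win[which.max(x[win])]
    keep_t <- c(keep_t, ext)
    keep_a <- c(keep_a, abs(x[ext]))
  }
  cbind(keep_t, keep_a)
}

#' Detect spikes by adaptive threshold crossing
#'
#' A spike is registered at each negative-going crossing of
#' `-(noise_multiplier x baseline noise SD)`; the spike time is the extremum
#' within `dead_time` after the crossing and the amplitude its absolute
#' value. Crossings within `dead_time` of a previous one are absorbed.
#'
#' @inheritParams estimate_noise_sd
#' @return A [spike_train()] carrying the threshold used.
#' @export
detect_spikes <- function(rec, params = detection_params()) {
  stop_if_not(length(rec$samples) > 0, "empty trace")
  stop_if_not(all(is.finite(rec$samples)), "non-finite samples in trace")
  sdN <- estimate_noise_sd(rec, params)
  thr <- params$noise_multiplier * sdN
  fs <- rec$sampling_rate
  dead <- max(1L, round(params$dead_time * fs))
  hits <- crossings_one_sign(rec$samples, -thr, dead, negative = TRUE)
  if (params$polarity == "both") {
    hits2 <- crossings_one_sign(rec$samples, thr, dead, negative = FALSE)
    hits <- rbind(hits, hits2)
    if (!is.null(hits) && nrow(hits) > 1) {
      hits <- hits[order(hits[, 1]), , drop = FALSE]
      ## absorb cross-polarity events inside the dead time
      keep <- c(TRUE, diff(hits[, 1]) >= dead)
      hits <- hits[keep, , drop = FALSE]
    }
  }
  if (is.null(hits) || !nrow(hits)) {
    return(spike_train(numeric(0), numeric(0),
                       duration = length(rec$samples) / fs, well = rec$well,
                       electrode = rec$electrode, div = rec$div,
                       genotype = rec$genotype, batch = rec$batch,
                       threshold_used = thr))
  }
  spike_train((hits[, 1] - 1) / fs, hits[, 2],
              duration = length(rec$samples) / fs, well = rec$well,
              electrode = rec$electrode, div = rec$div,
              genotype = rec$genotype, batch = rec$batch,
              threshold_used = thr)
}

#' Electrode activity criterion
#'
#' An electrode is active when it fires at least `rate_min` spikes per minute
#' and at least one spike reaches `amp_min` microvolts. The amplitude rule
#' gates the electrode, not individual spikes.
#'
#' @param train a [spike_train()].
#' @param rate_min minimum firing rate, spikes/min.
#' @param amp_min minimum spike amplitude, microvolts.
#' @export
electrode_is_active <- function(train, rate_min = 10, amp_min = 20) {
  stop_if_not(train$duration > 0, "duration must be positive")
  n <- length(train$times)
  if (n == 0) return(FALSE)
  rate_per_min <- n / train$duration * 60
  amp_ok <- if (all(is.na(train$amplitudes))) TRUE
            else any(train$amplitudes >= amp_min, na.rm = TRUE)
  rate_per_min >= rate_min && amp_ok
}

#' Well activity criterion
#'
#' A well is active when at least one of its electrodes is active.
#'
#' @param trains list of [spike_train()] for one well.
#' @inheritParams electrode_is_active
#' @export
well_is_active <- function(trains, rate_min = 10, amp_min = 20) {
  any(vapply(trains, electrode_is_active, logical(1),
             rate_min = rate_min, amp_min = amp_min))
}
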