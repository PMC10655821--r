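#' Plate specification
#'
#' Geometry and recording schedule of a multiwell MEA plate: by default a
#' 24-well plate with 12 electrodes per well, daily 5-minute recordings
#' sampled at 20 kHz from DIV 4 to DIV 42.
#'
#' @param n_wells wells on the plate.
#' @param electrodes_per_well electrodes per well.
#' @param duration recording duration in seconds.
#' @param sampling_rate samples per second for rendered voltage.
#' @param divs recording days.
#' @export
plate_spec <- function(n_wells = 24L, electrodes_per_well = 12L,
                       duration = 300, sampling_rate = 20000, divs = 4:42) {
  stop_if_not(duration > 0, "duration must be positive")
  stop_if_not(n_wells >= 1 && electrodes_per_well >= 1, "invalid plate geometry")
  structure(list(n_wells = as.integer(n_wells),
                 electrodes_per_well = as.integer(electrodes_per_well),
                 duration = duration, sampling_rate = sampling_rate,
                 divs = divs),
            class = "plate_spec")
}

#' Spike train container
#'
#' @param times spike times in seconds from recording start, sorted.
#' @param amplitudes peak absolute deflection per spike, microvolts.
#' @param duration recording duration, seconds.
#' @param well,electrode,div,genotype,batch recording metadata.
#' @param threshold_used detection threshold in microvolts (NA for
#'   ground-truth trains).
#' @export
spike_train <- function(times, amplitudes = rep(NA_real_, length(times)),
                        duration, well = 1L, electrode = 1L, div = NA,
                        genotype = NA_character_, batch = NA_character_,
                        threshold_used = NA_real_) {
  stop_if_not(!is.unsorted(times), "spike times must be sorted")
  stop_if_not(length(times) == length(amplitudes),
              "times and amplitudes must have equal length")
  stop_if_not(all(times >= 0 & times <= duration + 1e-9),
              "spike times must lie within [0, duration]")
  structure(list(times = as.numeric(times), amplitudes = as.numeric(amplitudes),
                 duration = duration, well = well, electrode = electrode,
                 div = div, genotype = genotype, batch = batch,
                 threshold_used = threshold_used),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> well %s el %s div %s: %d spikes in %g s (%.2f Hz)\n",
              x$well, x$electrode, x$div, length(x$times), x$duration,
              length(x$times) / x$duration))
  invisible(x)
}

## place n interval onsets in [lo, hi] such that intervals of length dur keep
## a minimum gap to already-placed intervals; rejection with a retry cap
place_intervals <- function(n, lo, hi, dur, existing_start, existing_end,
                            min_gap = 0.15, max_try = 60L) {
  starts <- existing_start
  ends <- existing_end
  placed <- numeric(0)
  if (hi <= lo) return(placed)
  for (i in seq_len(n)) {
    for (k in seq_len(max_try)) {
      s <- stats::runif(1, lo, hi)
      if (!length(starts) ||
          all(s + dur + min_gap < starts | s > ends + min_gap)) {
        starts <- c(starts, s)
        ends <- c(ends, s + dur)
        placed <- c(placed, s)
        break
      }
    }
  }
  placed
}

## amplitude models: healthy electrodes sit comfortably above the 20 uV
## activity criterion, silent electrodes below it
draw_amplitudes <- function(n, healthy) {
  if (healthy) rnorm_trunc(n, 60, 10, lower = 25)
  else rnorm_trunc(n, 14, 3, lower = 5, upper = 18)
}

#' Simulate ground-truth spike trains for a plate
#'
#' Per electrode and day, activity is the superposition of a homogeneous
#' Poisson background ("tonic") train and burst events: regular trains at the
#' profile's intra-burst interval. Bursts arrive as a Poisson process at the
#' electrode's own burst rate, plus well-wide network events at the profile's
#' network rate that recruit every healthy electrode (onsets jittered within
#' +/-10 ms). Burst intervals on one electrode keep a minimum 150 ms gap, so
#' each generated burst maps one-to-one to a detectable max-interval burst.
#' Electrodes are independently silent with probability
#' `1 - active_electrode_prob`; silent electrodes have tonic and burst rates
#' scaled by 0.02, draw sub-criterion spike amplitudes, and do not join
#' network events. The first `baseline` seconds are kept spike free (rates are
#' rescaled so expected counts over the full duration are unchanged).
#'
#' @param profile a [culture_profile()].
#' @param plate a [plate_spec()].
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @param divs days to simulate (defaults to `plate$divs`).
#' @param batch batch label recorded in metadata.
#' @param baseline leading spike-free window in seconds (0 disables).
#' @param silent_scale rate scaling for silent electrodes.
#' @return A list of class `mea_simulation` with elements `trains` (list of
#'   [spike_train()]), `truth` (list with closed-form `features`, per-burst
#'   `bursts`, and well-level `network` tables) and the call metadata.
#' @export
simulate_spike_trains <- function(profile, plate = plate_spec(), seed = 1L,
                                  divs = NULL, batch = "b1", baseline = 1,
                                  silent_scale = 0.02) {
  stop_if_not(inherits(profile, "culture_profile"), "not a culture_profile")
  divs <- divs %||% plate$divs
  set.seed(seed)
  T <- plate$duration
  t0 <- min(baseline, T / 2)
  rf <- T / (T - t0)  # rate rescale preserving expected counts
  n_el <- plate$electrodes_per_well
  trains <- list()
  burst_rows <- list()
  net_rows <- list()
  for (div in divs) {
    pp <- profile_params(profile, div)
    r_nbe <- pp$network_burst_rate * pmin(1, pp$network_participation)
    r_own <- max(pp$burst_rate - r_nbe, 0)
    isi <- pp$intra_burst_isi
    n_own <- burst_spike_count(pp$burst_duration, isi)
    n_net <- burst_spike_count(pp$network_burst_duration, isi)
    span_own <- if (n_own > 0) isi * (n_own - 1) else 0
    span_net <- if (n_net > 0) isi * (n_net - 1) else 0
    for (w in seq_len(plate$n_wells)) {
      healthy <- stats::runif(n_el) < pp$active_electrode_prob
      ## well-level network events
      ev_start <- numeric(0)
      if (pp$network_burst_rate > 0 && sum(healthy) > 0 && span_net > 0) {
        n_ev <- stats::rpois(1, pp$network_burst_rate / 60 * T)
        ev_start <- sort(place_intervals(n_ev, t0, T - span_net - 0.011,
                                         span_net, numeric(0), numeric(0)))
      }
      ## per-event participant sets: a random subset of healthy electrodes of
      ## size >= network_participation x electrodes (capped by healthy count)
      part_sets <- lapply(ev_start, function(s) {
        cand <- which(healthy)
        size <- min(length(cand),
                    max(3L, ceiling(pp$network_participation * n_el)))
        if (size < length(cand)) sort(sample(cand, size)) else cand
      })
      el_spikes <- vector("list", n_el)
      for (e in seq_len(n_el)) {
        scale <- if (healthy[e]) 1 else silent_scale
        ## network participation bursts
        my_ev <- numeric(0)
        if (length(ev_start)) {
          takes <- vapply(part_sets, function(p) e %in% p, logical(1))
          my_ev <- ev_start[takes]
        }
        ev_onset <- if (length(my_ev)) {
          pmax(pmin(my_ev + stats::runif(length(my_ev), -0.01, 0.01),
                    T - span_net), t0)
        } else numeric(0)
        ## own bursts
        own_onset <- numeric(0)
        if (r_own > 0 && n_own > 0) {
          n_b <- stats::rpois(1, r_own * scale / 60 * (T - t0) * rf)
          own_onset <- place_intervals(n_b, t0, T - span_own, span_own,
                                       ev_onset, ev_onset + span_net)
        }
        ## tonic background
        n_t <- stats::rpois(1, pp$tonic_rate * scale * (T - t0) * rf)
        tonic_t <- stats::runif(n_t, t0, T)
        b_times <- c(
          if (length(own_onset)) rep(own_onset, each = n_own) +
            rep(isi * (seq_len(n_own) - 1), times = length(own_onset)),
          if (length(ev_onset)) rep(ev_onset, each = n_net) +
            rep(isi * (seq_len(n_net) - 1), times = length(ev_onset)))
        all_t <- c(tonic_t, b_times)
        ord <- order(all_t)
        in_burst <- c(rep(FALSE, n_t), rep(TRUE, length(b_times)))[ord]
        all_t <- all_t[ord]
        amps <- draw_amplitudes(length(all_t), healthy[e])
        tr <- spike_train(all_t, amps, duration = T, well = w, electrode = e,
                          div = div, genotype = profile$genotype, batch = batch)
        attr(tr, "in_burst") <- in_burst
        attr(tr, "healthy") <- healthy[e]
        el_spikes[[e]] <- tr
        if (length(own_onset)) {
          burst_rows[[length(burst_rows) + 1L]] <- data.frame(
            well = w, electrode = e, div = div,
            t_start = sort(own_onset), t_end = sort(own_onset) + span_own,
            n_spikes = n_own, network = FALSE)
        }
        if (length(ev_onset)) {
          burst_rows[[length(burst_rows) + 1L]] <- data.frame(
            well = w, electrode = e, div = div,
            t_start = ev_onset, t_end = ev_onset + span_net,
            n_spikes = n_net, network = TRUE)
        }
      }
      trains <- c(trains, el_spikes)
      if (length(ev_start)) {
        net_rows[[length(net_rows) + 1L]] <- data.frame(
          well = w, div = div, t_start = ev_start, t_end = ev_start + span_net,
          n_electrodes = vapply(part_sets, length, integer(1)))
      }
    }
  }
  truth_features <- profile_truth(profile, divs, n_electrodes = n_el)
  structure(list(trains = trains,
                 truth = list(
                   features = truth_features,
                   bursts = if (length(burst_rows)) do.call(rbind, burst_rows)
                            else NULL,
                   network = if (length(net_rows)) do.call(rbind, net_rows)
                             else NULL),
                 plate = plate, profile = profile$genotype, seed = seed),
            class = "mea_simulation")
}

## biphasic extracellular spike template: negative-leading, 1.5 ms total
## width, normalized so the minimum is -1
spike_template <- function(sampling_rate) {
  t_ms <- (seq_len(round(0.0015 * sampling_rate)) - 1) / sampling_rate * 1000
  w <- -exp(-((t_ms - 0.4) / 0.18)^2) + 0.35 * exp(-((t_ms - 0.9) / 0.28)^2)
  w / abs(min(w))
}

#' Render a spike train as an extracellular voltage trace
#'
#' The trace is white Gaussian noise plus a biphasic (negative-leading,
#' 1.5 ms wide) template centered, at its negative peak, on each spike time
#' and scaled to the spike's amplitude. Emulates an already band-filtered
#' recording; spike times within the simulator's clean baseline window are
#' assumed absent (the generator guarantees this unless disabled).
#'
#' @param train a [spike_train()] (amplitudes must be positive).
#' @param noise_sd noise standard deviation, microvolts.
#' @param sampling_rate samples per second.
#' @param seed optional seed for the noise draw.
#' @return A [voltage_recording()].
#' @export
render_voltage <- function(train, noise_sd = 8, sampling_rate = 20000,
                           seed = NULL) {
  stop_if_not(noise_sd >= 0, "noise_sd must be non-negative")
  amps <- train$amplitudes
  if (length(amps)) {
    stop_if_not(!anyNA(amps) && all(amps > 0),
                "spike amplitudes must be positive to render voltage")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- round(train$duration * sampling_rate)
  x <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else numeric(n)
  tmpl <- spike_template(sampling_rate)
  peak_at <- which.min(tmpl)  # negative peak sample within the template
  if (length(train$times)) {
    centers <- round(train$times * sampling_rate) + 1L
    for (i in seq_along(centers)) {
      idx <- centers[i] - peak_at + seq_along(tmpl)
      keep <- idx >= 1L & idx <= n
      x[idx[keep]] <- x[idx[keep]] + amps[i] * tmpl[keep]
    }
  }
  voltage_recording(x, sampling_rate, well = train$well,
                    electrode = train$electrode, div = train$div,
                    genotype = train$genotype, batch = train$batch)
}

#' Zero-inflated beta simulation settings
#'
#' Describes a bounded-proportion assay (e.g. fluorescent puncta area
#' normalized to cell area) measured per cell in several independent culture
#' batches, two groups, across days. Responses are exactly zero with a
#' probability given by a logit-linear model in DIV and otherwise drawn from
#' a mean-precision Beta whose logit mean is linear in group, DIV and their
#' interaction plus a Gaussian batch random intercept.
#'
#' @param n_batches independent batches per group.
#' @param cells_per_batch_per_group cells measured per batch and group.
#' @param divs assay days.
#' @param zero_coef logit-scale coefficients (intercept, div) of the
#'   zero-probability model.
#' @param mean_coef logit-scale coefficients (intercept, group, div,
#'   group x div) of the beta mean model.
#' @param precision beta precision phi (> 0).
#' @param batch_sd SD of the batch random intercept on the logit scale.
#' @export
zib_sim_spec <- function(n_batches = 3L, cells_per_batch_per_group = 500L,
                         divs = c(14, 28, 42),
                         zero_coef = c(-2.5, 0.05),
                         mean_coef = c(-2.0, 0.4, 0.01, -0.02),
                         precision = 10, batch_sd = 0.4) {
  stop_if_not(precision > 0, "precision phi must be > 0")
  stop_if_not(batch_sd >= 0, "batch_sd must be >= 0")
  structure(list(n_batches = as.integer(n_batches),
                 cells_per_batch_per_group = as.integer(cells_per_batch_per_group),
                 divs = divs, zero_coef = zero_coef, mean_coef = mean_coef,
                 precision = precision, batch_sd = batch_sd),
            class = "zib_sim_spec")
}

#' Simulate a bounded-proportion dataset with excess zeros
#'
#' @param spec a [zib_sim_spec()].
#' @param seed integer seed.
#' @return data.frame with columns `response` (in \[0, 1)), `group` (0/1),
#'   `div`, `batch`.
#' @export
simulate_zib_dataset <- function(spec, seed = 1L) {
  stop_if_not(inherits(spec, "zib_sim_spec"), "not a zib_sim_spec")
  set.seed(seed)
  u <- stats::rnorm(spec$n_batches, 0, spec$batch_sd)
  rows <- expand.grid(cell = seq_len(spec$cells_per_batch_per_group),
                      div = spec$divs, group = c(0, 1),
                      batch = seq_len(spec$n_batches))
  eta_zero <- spec$zero_coef[1] + spec$zero_coef[2] * rows$div
  eta_mean <- spec$mean_coef[1] + spec$mean_coef[2] * rows$group +
    spec$mean_coef[3] * rows$div + spec$mean_coef[4] * rows$group * rows$div +
    u[rows$batch]
  pi0 <- stats::plogis(eta_zero)
  mu <- stats::plogis(eta_mean)
  phi <- spec$precision
  y <- stats::rbeta(nrow(rows), mu * phi, (1 - mu) * phi)
  ## beta support is open: resample the (measure-zero, numerically possible)
  ## boundary values
  bad <- which(y >= 1 | y <= 0)
  while (length(bad)) {
    y[bad] <- stats::rbeta(length(bad), mu[bad] * phi, (1 - mu[bad]) * phi)
    bad <- bad[y[bad] >= 1 | y[bad] <= 0]
  }
  zero <- stats::runif(nrow(rows)) < pi0
  y[zero] <- 0
  data.frame(response = y, group = rows$group, div = rows$div,
             batch = paste0("batch", rows$batch))
}
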