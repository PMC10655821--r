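#' Per-electrode activity features
#'
#' Computes spike rate (mean over fixed-width bins of bin counts), mean
#' interspike interval, burst rate, mean burst duration, percentage of spikes
#' inside bursts, and mean interburst interval (end of one burst to start of
#' the next). Features whose defining events are absent are `NA`, except
#' `pct_spikes_in_bursts`, which is a true 0 when spikes exist but no bursts.
#'
#' @param train a [spike_train()].
#' @param bursts data.frame from [detect_bursts()] for the same electrode.
#' @param rate_bin bin width in seconds for the rate estimate.
#' @return One-row data.frame.
#' @export
electrode_features <- function(train, bursts, rate_bin = 1) {
  t <- train$times
  dur <- train$duration
  nb <- nrow(bursts)
  n_bins <- max(1L, floor(dur / rate_bin + 1e-9))
  counts <- tabulate(pmin(floor(t / rate_bin) + 1L, n_bins), nbins = n_bins)
  in_burst <- 0L
  if (nb > 0 && length(t)) {
    for (i in seq_len(nb)) {
      in_burst <- in_burst +
        sum(t >= bursts$t_start[i] - 1e-12 & t <= bursts$t_end[i] + 1e-12)
    }
  }
  data.frame(
    well = train$well, electrode = train$electrode, div = train$div,
    genotype = train$genotype, batch = train$batch,
    spike_rate = mean(counts) / rate_bin,
    mean_isi = if (length(t) >= 2) mean(diff(t)) else NA_real_,
    burst_rate = nb / (dur / 60),
    burst_duration = if (nb > 0) mean(bursts$t_end - bursts$t_start)
                     else NA_real_,
    pct_spikes_in_bursts = if (length(t)) 100 * in_burst / length(t)
                           else NA_real_,
    mean_ibi = if (nb >= 2) mean(bursts$t_start[-1] - bursts$t_end[-nb])
               else NA_real_)
}

#' Well-average features over active electrodes
#'
#' Per-electrode features are averaged over the well's active electrodes
#' only (see [electrode_is_active()]); inactive wells yield no record.
#' Network-burst rate and duration are computed at the well level from the
#' network-burst table (a network burst is not an electrode property, so
#' those two features are not re-averaged).
#'
#' @param trains list of the well's [spike_train()]s.
#' @param bursts_by_electrode list of [detect_bursts()] tables parallel to
#'   `trains`.
#' @param network data.frame from [detect_network_bursts()] for the well.
#' @param n_electrodes electrodes per well for the percentage (default 12).
#' @param rate_bin rate bin width, seconds.
#' @return A one-row data.frame of well features, or `NULL` when the well
#'   has no active electrode.
#' @export
well_average <- function(trains, bursts_by_electrode, network = NULL,
                         n_electrodes = 12L, rate_bin = 1) {
  stop_if_not(length(trains) >= 1, "no electrodes supplied")
  active <- vapply(trains, electrode_is_active, logical(1))
  if (!any(active)) return(NULL)
  recs <- do.call(rbind, lapply(which(active), function(e) {
    electrode_features(trains[[e]], bursts_by_electrode[[e]],
                       rate_bin = rate_bin)
  }))
  dur <- trains[[1]]$duration
  feat_cols <- c("spike_rate", "mean_isi", "burst_rate", "burst_duration",
                 "pct_spikes_in_bursts", "mean_ibi")
  avg <- lapply(feat_cols, function(f) {
    v <- recs[[f]]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  names(avg) <- feat_cols
  n_net <- if (is.null(network)) 0L else nrow(network)
  out <- data.frame(
    well = trains[[1]]$well, div = trains[[1]]$div,
    genotype = trains[[1]]$genotype, batch = trains[[1]]$batch,
    pct_active_electrodes = 100 * sum(active) / n_electrodes)
  out <- cbind(out, as.data.frame(avg))
  out$network_burst_rate <- n_net / (dur / 60)
  out$network_burst_duration <-
    if (n_net > 0) mean(network$t_end - network$t_start) else NA_real_
  out
}

#' Feature table for a simulated or detected plate
#'
#' Runs burst detection, network-burst detection and well averaging over a
#' set of spike trains grouped by well and day, producing one row per active
#' well per day (the WellFeatures table used by the trajectory models).
#'
#' @param trains list of [spike_train()]s (e.g. `sim$trains` from
#'   [simulate_spike_trains()], or detected trains).
#' @param burst_par a [burst_params()].
#' @param min_electrodes network-burst synchrony threshold.
#' @param n_electrodes electrodes per well.
#' @param rate_bin rate bin width, seconds.
#' @return data.frame of well features.
#' @export
mea_features <- function(trains, burst_par = burst_params(),
                         min_electrodes = 3L, n_electrodes = 12L,
                         rate_bin = 1) {
  if (inherits(trains, "mea_simulation")) trains <- trains$trains
  key <- vapply(trains, function(tr) paste(tr$div, tr$well, sep = "|"),
                character(1))
  rows <- lapply(split(seq_along(trains), key), function(ix) {
    tl <- trains[ix]
    bl <- lapply(tl, detect_bursts, params = burst_par)
    ab <- do.call(rbind, bl)
    net <- detect_network_bursts(ab, min_electrodes = min_electrodes,
                                 min_ibi = burst_par$min_ibi,
                                 n_electrodes = n_electrodes, trains = tl)
    well_average(tl, bl, net, n_electrodes = n_electrodes,
                 rate_bin = rate_bin)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- do.call(rbind, rows)
  if (!is.null(out)) {
    out <- out[order(out$div, out$well), ]
    rownames(out) <- NULL
  }
  out
}

#' Phase mean of a well feature over a DIV window
#'
#' Mean of the per-well daily values of `feature` over wells of `genotype`
#' (all genotypes when `NULL`) and days within `div_range` inclusive.
#'
#' @param features WellFeatures table from [mea_features()].
#' @param feature feature column name.
#' @param div_range numeric length-2 inclusive day window.
#' @param genotype optional genotype filter.
#' @return The mean, or `NA` (with a warning) when the selection is empty.
#' @export
phase_mean <- function(features, feature, div_range, genotype = NULL) {
  stop_if_not(feature %in% names(features),
              sprintf("unknown feature '%s'", feature))
  sel <- features$div >= div_range[1] & features$div <= div_range[2]
  if (!is.null(genotype)) sel <- sel & features$genotype == genotype
  v <- features[[feature]][sel]
  v <- v[!is.na(v)]
  if (!length(v)) {
    warning("empty selection in phase_mean", call. = FALSE)
    return(NA_real_)
  }
  mean(v)
}
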