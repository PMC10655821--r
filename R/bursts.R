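#' Max-interval burst detection parameters
#'
#' Defaults are the standard multiwell MEA thresholds: maximum interval to
#' start a burst 50 ms, maximum interval to end a burst 50 ms, minimum
#' interval between bursts 100 ms, minimum burst duration 50 ms, minimum
#' spike count 4.
#'
#' @param max_isi_start largest ISI (s) that opens a burst.
#' @param max_isi_end largest ISI (s) that extends a burst.
#' @param min_ibi bursts closer than this gap (s) are merged.
#' @param min_duration bursts shorter than this (s) are discarded.
#' @param min_spikes bursts with fewer spikes are discarded.
#' @export
burst_params <- function(max_isi_start = 0.05, max_isi_end = 0.05,
                         min_ibi = 0.1, min_duration = 0.05, min_spikes = 4L) {
  stop_if_not(all(c(max_isi_start, max_isi_end, min_ibi, min_duration) > 0) &&
                min_spikes > 0, "all burst parameters must be positive")
  stop_if_not(min_ibi >= max_isi_end, "min_ibi must be >= max_isi_end")
  structure(list(max_isi_start = max_isi_start, max_isi_end = max_isi_end,
                 min_ibi = min_ibi, min_duration = min_duration,
                 min_spikes = as.integer(min_spikes)),
            class = "burst_params")
}

#' Detect single-electrode bursts (max-interval method)
#'
#' Three phases: (1) core detection — a candidate burst opens at a spike
#' whose ISI to the next spike is at most `max_isi_start` and extends while
#' successive ISIs are at most `max_isi_end`; (2) merging — consecutive
#' candidates whose gap (next start minus previous end) is below `min_ibi`
#' are merged; (3) filtering — candidates shorter than `min_duration` or with
#' fewer than `min_spikes` spikes are discarded. Burst boundaries are the
#' first and last spike times.
#'
#' @param train a [spike_train()] (times sorted).
#' @param params a [burst_params()].
#' @return data.frame with columns `t_start`, `t_end`, `n_spikes` plus the
#'   train's metadata columns; zero rows when no burst is found.
#' @export
detect_bursts <- function(train, params = burst_params()) {
  t <- train$times
  stop_if_not(!is.unsorted(t), "spike times must be sorted")
  empty <- data.frame(well = train$well[0], electrode = train$electrode[0],
                      div = train$div[0], t_start = numeric(0),
                      t_end = numeric(0), n_spikes = integer(0))
  n <- length(t)
  if (n < 2) return(empty)
  isi <- diff(t)
  ext <- isi <= params$max_isi_end
  r <- rle(ext)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  starts <- integer(0); ends <- integer(0)
  for (k in which(r$values)) {
    a <- run_start[k]; b <- run_end[k]
    ## burst must open with an ISI <= max_isi_start
    open <- a - 1L + which(isi[a:b] <= params$max_isi_start)[1]
    if (is.na(open)) next
    starts <- c(starts, open)
    ends <- c(ends, b + 1L)  # spike index ending the run
  }
  if (!length(starts)) return(empty)
  ## phase 2: merge candidates separated by < min_ibi
  if (length(starts) > 1) {
    gap <- t[starts[-1]] - t[ends[-length(ends)]]
    grp <- cumsum(c(0, gap >= params$min_ibi))
    starts <- tapply(starts, grp, min)
    ends <- tapply(ends, grp, max)
  }
  ## phase 3: filter on duration and spike count
  dur <- t[ends] - t[starts]
  n_sp <- ends - starts + 1L
  keep <- dur >= params$min_duration - 1e-12 & n_sp >= params$min_spikes
  if (!any(keep)) return(empty)
  data.frame(well = train$well, electrode = train$electrode, div = train$div,
             t_start = as.numeric(t[starts][keep]),
             t_end = as.numeric(t[ends][keep]),
             n_spikes = as.integer(n_sp[keep]), row.names = NULL)
}

#' Detect network bursts from per-electrode bursts
#'
#' Computes the burst-occupancy count over time (how many electrodes are
#' inside a single-electrode burst, intervals taken half-open) by an exact
#' interval sweep. A network burst is each maximal interval during which at
#' least `min_electrodes` electrodes burst simultaneously; network bursts
#' separated by less than `min_ibi` are merged. The electrode set is the
#' union of electrodes bursting during the interval.
#'
#' @param bursts data.frame of single-electrode bursts for one well and one
#'   recording (columns `electrode`, `t_start`, `t_end`), e.g. row-bound
#'   output of [detect_bursts()].
#' @param min_electrodes synchrony threshold (default 3 of 12).
#' @param min_ibi merge gap in seconds.
#' @param n_electrodes electrodes per well (id validation).
#' @param trains optional list of the well's [spike_train()]s, used to count
#'   spikes inside each network interval.
#' @return data.frame with `t_start`, `t_end`, `n_electrodes`, `electrodes`
#'   (comma-separated ids) and `n_spikes` (NA when `trains` is missing).
#' @export
detect_network_bursts <- function(bursts, min_electrodes = 3L, min_ibi = 0.1,
                                  n_electrodes = 12L, trains = NULL) {
  empty <- data.frame(t_start = numeric(0), t_end = numeric(0),
                      n_electrodes = integer(0), electrodes = character(0),
                      n_spikes = numeric(0))
  if (is.null(bursts) || nrow(bursts) == 0) return(empty)
  stop_if_not(all(bursts$electrode >= 1 & bursts$electrode <= n_electrodes),
              sprintf("electrode ids must lie in 1-%d", n_electrodes))
  ## exact sweep over interval endpoints; at ties ends are processed first
  ## (intervals are half-open [start, end))
  ev_t <- c(bursts$t_start, bursts$t_end)
  ev_d <- c(rep(1L, nrow(bursts)), rep(-1L, nrow(bursts)))
  ord <- order(ev_t, ev_d)
  ev_t <- ev_t[ord]; ev_d <- ev_d[ord]
  occ <- cumsum(ev_d)
  on <- occ >= min_electrodes
  if (!any(on)) return(empty)
  ## maximal intervals with occupancy >= threshold
  r <- rle(on)
  seg_end <- cumsum(r$lengths)
  seg_start <- seg_end - r$lengths + 1L
  hit <- which(r$values)
  t_start <- ev_t[seg_start[hit]]
  t_end <- ev_t[pmin(seg_end[hit] + 1L, length(ev_t))]
  ## merge network bursts separated by < min_ibi
  if (length(t_start) > 1) {
    grp <- cumsum(c(0, t_start[-1] - t_end[-length(t_end)] >= min_ibi - 1e-9))
    t_start <- as.numeric(tapply(t_start, grp, min))
    t_end <- as.numeric(tapply(t_end, grp, max))
  }
  els <- lapply(seq_along(t_start), function(i) {
    sort(unique(bursts$electrode[bursts$t_start < t_end[i] &
                                   bursts$t_end > t_start[i]]))
  })
  n_sp <- rep(NA_real_, length(t_start))
  if (!is.null(trains)) {
    all_t <- sort(unlist(lapply(trains, function(tr) tr$times)))
    n_sp <- vapply(seq_along(t_start), function(i) {
      sum(all_t >= t_start[i] & all_t < t_end[i])
    }, numeric(1))
  }
  data.frame(t_start = t_start, t_end = t_end,
             n_electrodes = vapply(els, length, integer(1)),
             electrodes = vapply(els, paste, character(1), collapse = ","),
             n_spikes = n_sp, row.names = NULL)
}
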