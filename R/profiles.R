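#' Culture activity profiles
#'
#' A `culture_profile` describes the ground-truth activity of a developing
#' neuronal culture as piecewise-linear trajectories of generator parameters
#' over days in vitro (DIV). The parameters at each anchor day are
#'
#' * `tonic_rate` (Hz): rate of the homogeneous Poisson background train,
#' * `burst_rate` (bursts/min): total per-electrode burst rate, including
#'   participation in well-wide network events,
#' * `burst_duration` (s): duration of an electrode's own (non-network) bursts,
#' * `intra_burst_isi` (s): regular interspike interval inside a burst,
#' * `active_electrode_prob`: probability that an electrode is healthy
#'   (non-silent) on that day,
#' * `network_burst_rate` (events/min): well-level rate of synchronous
#'   network events,
#' * `network_burst_duration` (s): duration of a network event,
#' * `network_participation`: fraction of the well's electrodes recruited
#'   into a network event (healthy electrodes only).
#'
#' Between anchors every parameter is linearly interpolated; outside the
#' anchored range the nearest anchor value is held constant.
#'
#' @param anchors data.frame with a `div` column plus the parameter columns
#'   above (missing parameter columns default to 0, `network_participation`
#'   to 1).
#' @param genotype label carried through to simulated recordings.
#' @return An object of class `culture_profile`.
#' @seealso [make_profile()] for the shipped calibrated profiles.
#' @export
culture_profile <- function(anchors, genotype = "custom") {
  stop_if_not(is.data.frame(anchors) && nrow(anchors) >= 1,
              "anchors must be a data.frame with at least one row")
  stop_if_not("div" %in% names(anchors), "anchors must have a 'div' column")
  d <- anchors$div
  stop_if_not(!anyNA(d) && !is.unsorted(d, strictly = TRUE),
              "anchor divs must be sorted and free of duplicates")
  stop_if_not(all(d >= 4 & d <= 42), "anchor divs must lie in [4, 42]")
  fields <- c("tonic_rate", "burst_rate", "burst_duration", "intra_burst_isi",
              "active_electrode_prob", "network_burst_rate",
              "network_burst_duration", "network_participation")
  for (f in fields) {
    if (is.null(anchors[[f]])) {
      anchors[[f]] <- if (f == "network_participation") 1 else 0
    }
  }
  rates <- c("tonic_rate", "burst_rate", "burst_duration", "intra_burst_isi",
             "network_burst_rate", "network_burst_duration")
  stop_if_not(all(as.matrix(anchors[rates]) >= 0),
              "rates and durations must be non-negative")
  probs <- c("active_electrode_prob", "network_participation")
  stop_if_not(all(as.matrix(anchors[probs]) >= 0 & as.matrix(anchors[probs]) <= 1),
              "probabilities must lie in [0, 1]")
  structure(list(genotype = genotype,
                 anchors = anchors[c("div", fields)]),
            class = "culture_profile")
}

#' @export
print.culture_profile <- function(x, ...) {
  cat(sprintf("<culture_profile> genotype '%s', %d anchors over DIV %g-%g\n",
              x$genotype, nrow(x$anchors), min(x$anchors$div),
              max(x$anchors$div)))
  invisible(x)
}

#' Interpolated generator parameters at given days
#'
#' @param profile a [culture_profile()].
#' @param div numeric vector of days in vitro.
#' @return data.frame with one row per day.
#' @export
profile_params <- function(profile, div) {
  stop_if_not(inherits(profile, "culture_profile"), "not a culture_profile")
  a <- profile$anchors
  out <- data.frame(div = div)
  for (f in setdiff(names(a), "div")) {
    out[[f]] <- interp_anchor(a$div, a[[f]], div)
  }
  out
}

## expected number of spikes in a regular intra-burst train spanning dur
burst_spike_count <- function(dur, isi) {
  ifelse(isi > 0 & dur > 0, floor(dur / isi + 1e-9) + 1, 0)
}

## mean fraction of active electrodes conditional on the well being active:
## E[X/12 | X >= 1], X ~ Binomial(n_el, p)
pct_active_given_active_well <- function(p, n_el = 12L) {
  100 * n_el * p / (n_el * (1 - (1 - p)^n_el))
}

## invert pct_active_given_active_well for p
p_active_from_pct <- function(pct, n_el = 12L) {
  vapply(pct, function(target) {
    if (target <= 0) return(0)
    if (target >= 100) return(1)
    ## conditional on >= 1 active electrode the mean cannot drop below 1/n_el
    if (target <= 100 / n_el + 1e-9) return(1e-4)
    stats::uniroot(function(p) pct_active_given_active_well(p, n_el) - target,
                   c(1e-8, 1), tol = 1e-10)$root
  }, numeric(1))
}

#' Closed-form expected feature values implied by a profile
#'
#' Computes, without simulation, the feature values the analysis pipeline is
#' expected to recover from recordings generated under `profile`: total spike
#' rate, mean interspike interval, burst rate and mean burst duration (a
#' mixture of own and network-participation bursts), percentage of spikes in
#' bursts, mean interburst interval, well-level network burst rate and
#' duration, and the percentage of active electrodes conditional on the
#' active-well inclusion rule.
#'
#' @inheritParams profile_params
#' @param n_electrodes electrodes per well (activity conditioning).
#' @return data.frame with one row per day.
#' @export
profile_truth <- function(profile, div, n_electrodes = 12L) {
  p <- profile_params(profile, div)
  r_nbe <- p$network_burst_rate * pmin(1, p$network_participation)
  r_own <- pmax(p$burst_rate - r_nbe, 0)
  n_own <- burst_spike_count(p$burst_duration, p$intra_burst_isi)
  n_net <- burst_spike_count(p$network_burst_duration, p$intra_burst_isi)
  span_own <- p$intra_burst_isi * pmax(n_own - 1, 0)
  span_net <- p$intra_burst_isi * pmax(n_net - 1, 0)
  burst_hz <- (r_own * n_own + r_nbe * n_net) / 60
  spike_rate <- p$tonic_rate + burst_hz
  b_rate <- r_own + r_nbe
  b_dur <- ifelse(b_rate > 0, (r_own * span_own + r_nbe * span_net) / b_rate, NA)
  data.frame(
    div = div,
    genotype = profile$genotype,
    pct_active_electrodes =
      pct_active_given_active_well(p$active_electrode_prob, n_electrodes),
    spike_rate = spike_rate,
    mean_isi = ifelse(spike_rate > 0, 1 / spike_rate, NA),
    burst_rate = b_rate,
    burst_duration = b_dur,
    pct_spikes_in_bursts =
      ifelse(spike_rate > 0, 100 * burst_hz / spike_rate, NA),
    mean_ibi = ifelse(b_rate > 0,
                      pmax((60 - r_own * span_own - r_nbe * span_net), 0) / b_rate,
                      NA),
    network_burst_rate = p$network_burst_rate,
    network_burst_duration = ifelse(p$network_burst_rate > 0, span_net, NA)
  )
}

## ---- calibration of shipped profiles --------------------------------------

## solve the intra-burst ISI so the expected in-burst spike rate matches the
## target; the objective is a step function of isi, so scan a fine grid
solve_intra_isi <- function(target_hz, r_own, d_own, r_nbe, nbd,
                            isi_min = 0.003, isi_max = 0.045) {
  if (r_own + r_nbe <= 0 || target_hz <= 0) return(0.02)
  upper <- isi_max
  ## isi <= d_own/4 keeps own bursts at >= 5 spikes spanning >= 3/4 d_own,
  ## safely above the 50 ms / 4-spike detectability filters
  if (r_own > 0) upper <- min(upper, d_own / 4)
  upper <- max(upper, isi_min)
  grid <- seq(isi_min, upper, by = 1e-5)
  f <- (r_own * burst_spike_count(d_own, grid) +
          r_nbe * burst_spike_count(nbd, grid)) / 60
  grid[which.min(abs(f - target_hz))]
}

## convert one day's measured-feature targets into generator parameters
calibrate_day <- function(tg) {
  r_nbe <- tg$network_burst_rate
  r_own <- max(tg$burst_rate - r_nbe, 0)
  nbd <- tg$network_burst_duration
  if (r_own > 1e-9) {
    d_own <- (tg$burst_duration * tg$burst_rate - r_nbe * nbd) / r_own
    ## floor at 0.07 s: with isi <= d_own/4 the realized burst span
    ## (isi x floor(d_own/isi) >= 3/4 d_own) stays above the 50 ms
    ## minimum-duration detection filter
    d_own <- min(max(d_own, 0.07), 0.35)
  } else {
    d_own <- 0.07
  }
  target_burst_hz <- tg$spike_rate * tg$pct_spikes_in_bursts / 100
  isi <- solve_intra_isi(target_burst_hz, r_own, d_own, r_nbe, nbd)
  attained_hz <- (r_own * burst_spike_count(d_own, isi) +
                    r_nbe * burst_spike_count(nbd, isi)) / 60
  tonic <- max(tg$spike_rate - attained_hz, 0)
  data.frame(div = tg$div,
             tonic_rate = tonic,
             burst_rate = r_own + r_nbe,
             burst_duration = d_own,
             intra_burst_isi = isi,
             active_electrode_prob = p_active_from_pct(tg$pct_active_electrodes),
             network_burst_rate = r_nbe,
             network_burst_duration = nbd,
             network_participation = 1)
}

shipped_profile_path <- function(name) {
  system.file("extdata", "profiles", paste0(name, ".json"),
              package = "meadev", mustWork = FALSE)
}

read_feature_trajectories <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  divs <- seq(spec$div_range[1], spec$div_range[2])
  tg <- data.frame(div = divs)
  for (f in names(spec$trajectories)) {
    tr <- spec$trajectories[[f]]
    tg[[f]] <- interp_anchor(tr$div, tr$value, divs)
  }
  list(genotype = spec$genotype, targets = tg)
}

#' Construct a culture profile
#'
#' `make_profile("cln3")` and `make_profile("corrected")` return the two
#' shipped profiles, calibrated so that the feature values the pipeline
#' recovers reproduce the published developmental trajectories of the
#' CLN3-mutant and isogenic CRISPR-corrected cortical cultures (peak spike
#' rates, phase means of activity, burstiness and network synchrony).
#' Shipped profiles are stored as measured-feature anchor trajectories and
#' inverted day-by-day into generator parameters. Alternatively pass an
#' anchor table of generator parameters directly (see [culture_profile()]).
#'
#' @param name shipped profile id (`"cln3"` or `"corrected"`), a path to a
#'   profile JSON file, or a generator-parameter anchor data.frame.
#' @param genotype genotype label when `name` is an anchor table.
#' @return A `culture_profile`.
#' @examples
#' prof <- make_profile("corrected")
#' profile_truth(prof, 25)$spike_rate  # peak total spike rate, Hz
#' @export
make_profile <- function(name, genotype = "custom") {
  if (is.data.frame(name)) return(culture_profile(name, genotype))
  stop_if_not(is.character(name) && length(name) == 1, "invalid profile name")
  path <- if (file.exists(name)) name else shipped_profile_path(name)
  if (is.null(path) || !nzchar(path) || !file.exists(path)) {
    stop(sprintf("unknown profile id '%s' (shipped: 'cln3', 'corrected')", name),
         call. = FALSE)
  }
  traj <- read_feature_trajectories(path)
  rows <- lapply(seq_len(nrow(traj$targets)),
                 function(i) calibrate_day(traj$targets[i, ]))
  culture_profile(do.call(rbind, rows), genotype = traj$genotype)
}
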