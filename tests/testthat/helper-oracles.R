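## Independent oracles used by the test-suite. These deliberately use
## different mechanics from the package implementation.

## three-phase max-interval burst detection by explicit sequential scanning
oracle_bursts <- function(times, max_isi_start = 0.05, max_isi_end = 0.05,
                          min_ibi = 0.1, min_duration = 0.05, min_spikes = 4) {
  n <- length(times)
  cand <- list()
  i <- 1
  while (i < n) {
    if (times[i + 1] - times[i] <= max_isi_start) {
      j <- i + 1
      while (j < n && times[j + 1] - times[j] <= max_isi_end) j <- j + 1
      cand[[length(cand) + 1]] <- c(i, j)
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  if (!length(cand)) return(NULL)
  ## merge by repeated pairwise passes until stable
  repeat {
    merged <- FALSE
    k <- 1
    while (k < length(cand)) {
      gap <- times[cand[[k + 1]][1]] - times[cand[[k]][2]]
      if (gap < min_ibi) {
        cand[[k]] <- c(cand[[k]][1], cand[[k + 1]][2])
        cand[[k + 1]] <- NULL
        merged <- TRUE
      } else {
        k <- k + 1
      }
    }
    if (!merged) break
  }
  out <- do.call(rbind, lapply(cand, function(c2) {
    data.frame(t_start = times[c2[1]], t_end = times[c2[2]],
               n_spikes = c2[2] - c2[1] + 1)
  }))
  out <- out[out$t_end - out$t_start >= min_duration - 1e-12 &
               out$n_spikes >= min_spikes, , drop = FALSE]
  if (!nrow(out)) NULL else out
}

## network bursts by brute-force time-grid occupancy at 1 ms resolution
oracle_network_grid <- function(bursts, min_electrodes = 3, min_ibi = 0.1,
                                res = 0.001) {
  if (is.null(bursts) || !nrow(bursts)) return(NULL)
  t0 <- floor(min(bursts$t_start) / res) - 2
  t1 <- ceiling(max(bursts$t_end) / res) + 2
  grid <- (t0:t1) * res
  occ <- sapply(grid, function(t) {
    sum(bursts$t_start <= t + 1e-12 & bursts$t_end > t + 1e-12)
  })
  on <- occ >= min_electrodes
  if (!any(on)) return(NULL)
  r <- rle(on)
  e <- cumsum(r$lengths); s <- e - r$lengths + 1
  hit <- which(r$values)
  ts <- grid[s[hit]]
  te <- grid[e[hit]] + res
  if (length(ts) > 1) {
    grp <- cumsum(c(0, ts[-1] - te[-length(te)] >= min_ibi - 1e-9))
    ts <- as.numeric(tapply(ts, grp, min))
    te <- as.numeric(tapply(te, grp, max))
  }
  data.frame(t_start = ts, t_end = te)
}

## textbook zero-inflated beta log-likelihood (no random effect)
oracle_zib_ll <- function(beta, phi, gamma, data) {
  g <- data$group
  X <- cbind(1, g, data$div, g * data$div)
  mu <- 1 / (1 + exp(-drop(X %*% beta)))
  eta0 <- if (length(gamma) == 2) gamma[1] + gamma[2] * data$div
          else rep(gamma[1], nrow(data))
  pi0 <- 1 / (1 + exp(-eta0))
  y <- data$response
  sum(ifelse(y == 0, log(pi0),
             log(1 - pi0) + lgamma(phi) - lgamma(mu * phi) -
               lgamma((1 - mu) * phi) + (mu * phi - 1) * log(y) +
               ((1 - mu) * phi - 1) * log(1 - y)))
}

## plain beta regression ML (logit mean, log precision) via Nelder-Mead,
## independent of the package's likelihood code
oracle_betareg <- function(data) {
  g <- data$group
  X <- cbind(1, g, data$div, g * data$div)
  y <- data$response
  nll <- function(par) {
    mu <- 1 / (1 + exp(-drop(X %*% par[1:4])))
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    phi <- exp(par[5])
    -sum(lgamma(phi) - lgamma(mu * phi) - lgamma((1 - mu) * phi) +
           (mu * phi - 1) * log(y) + ((1 - mu) * phi - 1) * log(1 - y))
  }
  o <- stats::optim(c(0, 0, 0, 0, log(2)), nll, method = "BFGS",
                    control = list(maxit = 2000, reltol = 1e-12))
  list(beta = o$par[1:4], phi = exp(o$par[5]), logLik = -o$value)
}

## a plain generator-parameter profile for tests
test_profile <- function(tonic = 2, burst_rate = 6, burst_duration = 0.5,
                         isi = 0.02, p_active = 1, nb_rate = 0, nb_dur = 0,
                         participation = 1, genotype = "test") {
  culture_profile(data.frame(
    div = 4, tonic_rate = tonic, burst_rate = burst_rate,
    burst_duration = burst_duration, intra_burst_isi = isi,
    active_electrode_prob = p_active, network_burst_rate = nb_rate,
    network_burst_duration = nb_dur, network_participation = participation),
    genotype = genotype)
}

## quick spike train with given times
st <- function(times, duration = max(times, 1) + 1, amps = 60) {
  spike_train(times, rep(amps, length.out = length(times)),
              duration = duration)
}
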