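test_that("zero-rate profiles generate empty trains", {
  p <- test_profile(tonic = 0, burst_rate = 0)
  sim <- simulate_spike_trains(p, plate_spec(n_wells = 2, duration = 60),
                               seed = 1, divs = 10)
  expect_true(all(vapply(sim$trains, function(tr) length(tr$times),
                         integer(1)) == 0L))
})

test_that("tonic spike counts match the Poisson mean (2 Hz x 300 s = 600)", {
  p <- test_profile(tonic = 2, burst_rate = 0)
  ## 84 wells x 12 electrodes = 1008 electrodes
  sim <- simulate_spike_trains(p, plate_spec(n_wells = 84), seed = 7,
                               divs = 10)
  counts <- vapply(sim$trains, function(tr) length(tr$times), integer(1))
  se <- sqrt(600 / length(counts))
  expect_lt(abs(mean(counts) - 600), 2 * se)
})

test_that("generated bursts carry floor(dur/isi)+1 spikes and keep 150 ms gaps", {
  p <- test_profile(tonic = 0.5, burst_rate = 6, burst_duration = 0.5,
                    isi = 0.02)
  sim <- simulate_spike_trains(p, plate_spec(n_wells = 4), seed = 2, divs = 10)
  b <- sim$truth$bursts
  expect_true(all(b$n_spikes == 26))  # floor(0.5/0.02) + 1
  gaps <- unlist(lapply(split(b, paste(b$well, b$electrode)), function(d) {
    if (nrow(d) < 2) return(numeric(0))
    d <- d[order(d$t_start), ]
    d$t_start[-1] - d$t_end[-nrow(d)]
  }))
  expect_true(all(gaps >= 0.15 - 1e-9))
})

test_that("network events recruit >= 3 electrodes and stay synchronized", {
  p <- test_profile(tonic = 0.5, burst_rate = 4, burst_duration = 0.2,
                    isi = 0.02, nb_rate = 2, nb_dur = 1, participation = 0.5)
  sim <- simulate_spike_trains(p, plate_spec(n_wells = 4), seed = 3, divs = 10)
  net <- sim$truth$network
  expect_gt(nrow(net), 0)
  expect_true(all(net$n_electrodes >= 3))
  ## participant burst onsets lie within +/-10 ms of the event onset
  b <- sim$truth$bursts
  for (i in seq_len(min(nrow(net), 20))) {
    onsets <- b$t_start[b$network & b$well == net$well[i] &
                          abs(b$t_start - net$t_start[i]) < 0.5]
    expect_true(all(abs(onsets - net$t_start[i]) <= 0.0101))
  }
})

test_that("the same seed reproduces the simulation bit for bit", {
  p <- test_profile(nb_rate = 1, nb_dur = 0.5, burst_duration = 0.2)
  s1 <- simulate_spike_trains(p, plate_spec(n_wells = 2, duration = 60),
                              seed = 11, divs = c(10, 20))
  s2 <- simulate_spike_trains(p, plate_spec(n_wells = 2, duration = 60),
                              seed = 11, divs = c(10, 20))
  expect_identical(lapply(s1$trains, `[[`, "times"),
                   lapply(s2$trains, `[[`, "times"))
  expect_identical(s1$truth$bursts, s2$truth$bursts)
})

test_that("detected spike rate on burst-free trains is unbiased over seeds", {
  p <- test_profile(tonic = 1.5, burst_rate = 0)
  rates <- vapply(1:20, function(s) {
    sim <- simulate_spike_trains(p, plate_spec(n_wells = 1, duration = 120),
                                 seed = s, divs = 10)
    mean(vapply(sim$trains, function(tr) length(tr$times) / tr$duration,
                numeric(1)))
  }, numeric(1))
  se <- sd(rates) / sqrt(length(rates))
  expect_lt(abs(mean(rates) - 1.5), 3 * se)
})

test_that("zero-inflation simulation matches its stated law", {
  ## inverse-logit(0) = 0.5 zero probability
  sp <- zib_sim_spec(n_batches = 2, cells_per_batch_per_group = 850,
                     divs = c(14, 28, 42), zero_coef = c(0, 0),
                     batch_sd = 0)
  d <- simulate_zib_dataset(sp, seed = 4)
  n <- nrow(d)
  expect_gte(n, 10000)
  expect_lt(abs(mean(d$response == 0) - 0.5), 2 * sqrt(0.25 / n))
  ## mu = 0.5, phi = 2 gives uniform positives
  sp <- zib_sim_spec(n_batches = 2, cells_per_batch_per_group = 450,
                     divs = c(14, 28), zero_coef = c(-20, 0),
                     mean_coef = c(0, 0, 0, 0), precision = 2, batch_sd = 0)
  d <- simulate_zib_dataset(sp, seed = 5)
  y <- d$response[d$response > 0]
  expect_gte(length(y), 3000)
  ks <- suppressWarnings(ks.test(y, "punif"))
  expect_lt(unname(ks$statistic), 1.36 / sqrt(length(y)))
  ## batch random intercepts have roughly the configured spread
  sp <- zib_sim_spec(n_batches = 6, cells_per_batch_per_group = 800,
                     divs = 28, zero_coef = c(-20, 0),
                     mean_coef = c(0, 0, 0, 0), precision = 60,
                     batch_sd = 0.5)
  d <- simulate_zib_dataset(sp, seed = 11)
  bm <- tapply(qlogis(pmin(pmax(d$response, 1e-6), 1 - 1e-6)), d$batch, mean)
  expect_lt(abs(sd(bm) - 0.5), 0.25)
})
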