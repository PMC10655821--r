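test_that("single-observation contributions match closed forms", {
  d1 <- data.frame(response = 0, group = 0, div = 0, batch = "b1")
  expect_equal(zib_loglik(c(0, 0, 0, 0), 2, c(0, 0), 0, d1), log(0.5))
  d2 <- data.frame(response = 0.5, group = 0, div = 0, batch = "b1")
  expect_equal(zib_loglik(c(0, 0, 0, 0), 2, c(qlogis(0.2), 0), 0, d2),
               log(0.8))
  expect_error(zib_loglik(c(0, 0, 0, 0), 2, c(0, 0), 0,
                          data.frame(response = 1, group = 0, div = 0,
                                     batch = "b")), "\\[0, 1\\)")
  expect_error(zib_loglik(c(0, 0, 0, 0), -1, c(0, 0), 0, d2), "phi")
})

test_that("log-likelihood matches the textbook evaluation to 1e-10", {
  set.seed(31)
  sp <- zib_sim_spec(n_batches = 2, cells_per_batch_per_group = 10,
                     batch_sd = 0, divs = c(14, 28, 42))
  d <- simulate_zib_dataset(sp, seed = 5)   # about 120 observations
  d <- d[seq_len(50), ]
  ## div enters the linear predictors on its raw scale (14-42), so
  ## div-coefficients are drawn on a correspondingly smaller scale to keep
  ## the beta shapes non-degenerate
  for (i in 1:10) {
    beta <- c(rnorm(2, 0, 0.5), rnorm(2, 0, 0.02))
    phi <- exp(rnorm(1, 1, 0.5))
    gam <- c(rnorm(1, -1, 0.3), rnorm(1, 0, 0.01))
    expect_equal(zib_loglik(beta, phi, gam, 0, d),
                 oracle_zib_ll(beta, phi, gam, d), tolerance = 1e-10)
  }
})

test_that("the quadrature path agrees with the direct path as sigma_b -> 0", {
  sp <- zib_sim_spec(n_batches = 3, cells_per_batch_per_group = 30,
                     batch_sd = 0)
  d <- simulate_zib_dataset(sp, seed = 7)
  beta <- c(0.2, -0.5, 0.01, 0.02)
  ll0 <- zib_loglik(beta, 4, c(-1, 0.03), 0, d)
  llq <- zib_loglik(beta, 4, c(-1, 0.03), 1e-8, d)
  expect_equal(llq, ll0, tolerance = 1e-8)
})

test_that("with no zeros the fit reduces to plain beta regression", {
  sp <- zib_sim_spec(n_batches = 3, cells_per_batch_per_group = 100,
                     zero_coef = c(-30, 0), batch_sd = 0,
                     mean_coef = c(-1, 0.4, 0.01, -0.02), precision = 8)
  d <- simulate_zib_dataset(sp, seed = 3)
  expect_true(all(d$response > 0))
  fit <- suppressWarnings(fit_zib(d, zero_on_div = FALSE))
  expect_lte(fit$gamma[1], -19)              # pushed to the -20 bound
  expect_lt(plogis(fit$gamma[1]), 1e-8)      # estimated zero probability ~ 0
  o <- oracle_betareg(d)
  expect_equal(unname(fit$beta), o$beta, tolerance = 1e-3)
  expect_equal(fit$phi, o$phi, tolerance = 1e-3)
})

test_that("randomly permuted group labels give a null group effect", {
  sp <- zib_sim_spec(n_batches = 3, cells_per_batch_per_group = 150,
                     mean_coef = c(-1, 0.6, 0.01, -0.02), batch_sd = 0)
  d <- simulate_zib_dataset(sp, seed = 13)
  set.seed(14)
  d$group <- sample(d$group)
  fit <- fit_zib(d)
  ## null by construction; 3 SE keeps the check from tripping on the ~5%
  ## of permutations that land beyond 2 SE
  expect_lt(abs(fit$beta[2] / fit$se["beta.group"]), 3)
})

test_that("likelihood-ratio test arithmetic and guards", {
  sp <- zib_sim_spec(n_batches = 3, cells_per_batch_per_group = 60,
                     zero_coef = c(-1, 0.05), batch_sd = 0)
  d <- simulate_zib_dataset(sp, seed = 21)
  f0 <- fit_zib(d, zero_on_div = FALSE)
  f1 <- fit_zib(d, zero_on_div = TRUE)
  lr <- lrt_zero_process(f0, f1)
  expect_equal(lr$df, 1)
  expect_gte(lr$statistic, 0)
  expect_true(lr$p_value >= 0 && lr$p_value <= 1)
  ## identical likelihoods give statistic 0, p = 1
  f1b <- f0
  f1b$zero_on_div <- TRUE
  f1b$df <- f0$df + 1
  lr0 <- lrt_zero_process(f0, f1b)
  expect_equal(lr0$statistic, 0)
  expect_equal(lr0$p_value, 1)
  ## non-nested arguments are refused
  expect_error(lrt_zero_process(f1, f0), "nested")
})

test_that("a div-dependent zero process is detected with high power", {
  ## gamma_div = 0.08 over div 14-42, moderate n: strong signal
  sp <- zib_sim_spec(n_batches = 3, cells_per_batch_per_group = 200,
                     zero_coef = c(-2.5, 0.08), batch_sd = 0,
                     divs = c(14, 28, 42))
  rej <- 0
  for (r in 1:5) {
    d <- simulate_zib_dataset(sp, seed = 100 + r)
    f0 <- fit_zib(d, zero_on_div = FALSE)
    f1 <- fit_zib(d, zero_on_div = TRUE)
    rej <- rej + (lrt_zero_process(f0, f1)$p_value < 0.05)
  }
  expect_gte(rej, 4)
})
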