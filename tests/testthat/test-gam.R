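test_that("the spline basis has full rank and the stated null space", {
  set.seed(4)
  for (i in 1:5) {
    x <- sort(sample(4:42, sample(10:30, 1)))
    basis <- build_spline_basis(x, k = 10)
    k <- length(basis$knots)
    expect_equal(qr(meadev:::cr_design(basis$knots, basis$knots))$rank, k)
    ## linear functions are unpenalized by the raw second-derivative penalty
    lin <- 2 + 0.3 * basis$knots   # cardinal basis: coefficients = values
    expect_lt(drop(lin %*% basis$S_raw %*% lin), 1e-8)
    ## but carry positive shrinkage penalty
    expect_gt(drop(lin %*% basis$S %*% lin), 0)
  }
  expect_error(build_spline_basis(c(4, 10, 20), k = 10), "4 distinct")
})

test_that("gaussian identity fits match the ridge closed form to 1e-8", {
  set.seed(42)
  n <- 120; x <- sample(4:42, n, TRUE); g <- sample(c("a", "b"), n, TRUE)
  y <- sin(x / 6) + (g == "b") * 0.5 + rnorm(n, 0, 0.3)
  df <- data.frame(div = x, genotype = g, resp = y)
  lam <- 3
  fit <- fit_gamma_gam(df, "resp", gam_config(family = "gaussian",
                                              lambda = lam))
  basis <- build_spline_basis(x, 10)
  k <- length(basis$knots)
  Z <- qr.Q(qr(matrix(colMeans(basis$X), k, 1)), complete = TRUE)[, -1,
                                                                  drop = FALSE]
  X <- meadev:::gam_design(x, g, basis$knots, basis$Fpad, Z, c("a", "b"))
  Ss <- t(Z) %*% basis$S %*% Z
  P <- matrix(0, ncol(X), ncol(X))
  for (gi in 0:1) {
    ix <- 2 + gi * ncol(Z) + seq_len(ncol(Z))
    P[ix, ix] <- Ss
  }
  beta_ridge <- solve(crossprod(X) + lam * P, crossprod(X, y))
  expect_lt(max(abs(drop(beta_ridge) - fit$coefficients)), 1e-8)
})

test_that("the gamma GAM recovers a known smooth trajectory", {
  set.seed(1)
  n <- 600; x <- runif(n, 4, 42)
  y <- rgamma(n, 5, rate = 5 / exp(1 + sin(x / 6)))
  fit <- fit_gamma_gam(data.frame(div = x, genotype = "a", resp = y), "resp")
  grid <- seq(5, 41, by = 0.5)
  pr <- predict(fit, grid)
  expect_lt(mean(abs(log(pr$fit) - (1 + sin(grid / 6)))), 0.1)
  expect_true(all(pr$lo < pr$fit & pr$fit < pr$hi))
})

test_that("shrinkage collapses the smooth in the smoothing limit", {
  set.seed(2)
  x <- runif(300, 4, 42)
  y <- rgamma(300, 5, rate = 5 / exp(1 + sin(x / 6)))
  df <- data.frame(div = x, genotype = "a", resp = y)
  fit_inf <- fit_gamma_gam(df, "resp", gam_config(lambda = 1e15))
  g0 <- glm(resp ~ 1, data = df, family = Gamma(link = "log"))
  expect_lt(abs(fit_inf$deviance - g0$deviance), 1e-6)
  ## constant response (plus tiny jitter): smooth edf collapses
  yc <- 5 + rnorm(300, 0, 1e-4)
  fit_c <- fit_gamma_gam(data.frame(div = x, genotype = "a", resp = yc),
                         "resp")
  expect_lte(fit_c$edf, 1.5 + 1)   # intercept + residual smooth edf <= 1.5
})

test_that("an unpenalized full-rank fit interpolates", {
  xs <- c(4, 9, 15, 22, 30, 42); ys <- c(1, 3, 2, 5, 4, 2.5)
  fit <- fit_gamma_gam(data.frame(div = xs, genotype = "a", resp = ys),
                       "resp", gam_config(k = 6, lambda = 0, eps = 0))
  expect_lt(max(abs(fit$fitted - ys)), 1e-6)
})

test_that("genotype differences behave under null, effect, and rescaling", {
  set.seed(8)
  divs <- 4:42; n_per <- 8
  x <- rep(divs, each = 2 * n_per)
  g <- rep(rep(c("a", "b"), each = n_per), length(divs))
  ## identical data under both labels -> zero difference
  y0 <- rep(rgamma(length(divs) * n_per, 5, 1), times = 1)
  ydup <- rep(NA_real_, length(x))
  ydup[g == "a"] <- y0; ydup[g == "b"] <- y0
  fit0 <- fit_gamma_gam(data.frame(div = x, genotype = g, resp = ydup), "resp")
  d0 <- genotype_difference(fit0, divs)
  expect_lt(max(abs(d0$diff)), 1e-8)
  expect_false(any(d0$significant))
  expect_error(genotype_difference(fit0, c(2, 10)), "extrapolation")
  ## constant two-fold ratio: the difference CI covers log 2 at >= 90% of
  ## grid points (averaged over replicates; a single realization has highly
  ## correlated pointwise errors)
  cov <- vapply(1:5, function(r) {
    mu <- exp(1 + sin(x / 6)) * ifelse(g == "b", 2, 1)
    yr <- rgamma(length(x), 5, rate = 5 / mu)
    fr <- fit_gamma_gam(data.frame(div = x, genotype = g, resp = yr), "resp")
    dr <- genotype_difference(fr, divs)
    mean(dr$lo <= log(2) & log(2) <= dr$hi)
  }, numeric(1))
  expect_gte(mean(cov), 0.9)
  ## GCV-selected lambda is invariant to response rescaling (log link)
  y2 <- rgamma(length(x), 5,
               rate = 5 / (exp(1 + sin(x / 6)) * ifelse(g == "b", 2, 1)))
  df <- data.frame(div = x, genotype = g, resp = y2)
  f1 <- fit_gamma_gam(df, "resp")
  df$resp <- df$resp * 10
  f10 <- fit_gamma_gam(df, "resp")
  expect_equal(f1$lambda, f10$lambda)
})

test_that("fitted curves agree with an independent GAM implementation", {
  skip_if_not_installed("mgcv")
  set.seed(5)
  x <- runif(500, 4, 42)
  y <- rgamma(500, 5, rate = 5 / exp(1 + sin(x / 6)))
  df <- data.frame(div = x, genotype = "a", resp = y)
  fit <- fit_gamma_gam(df, "resp")
  ref <- mgcv::gam(resp ~ s(div, bs = "cs", k = 10), data = df,
                   family = Gamma(link = "log"))
  grid <- seq(5, 41, by = 1)
  ours <- log(predict(fit, grid)$fit)
  theirs <- as.numeric(mgcv::predict.gam(ref, data.frame(div = grid),
                                         type = "link"))
  expect_lt(mean(abs(ours - theirs)), 0.05)
})

test_that("confidence bands tighten as the sample grows", {
  set.seed(12)
  width <- vapply(c(50, 200, 800), function(n) {
    x <- runif(n, 4, 42)
    y <- rgamma(n, 5, rate = 5 / exp(1 + sin(x / 6)))
    fit <- fit_gamma_gam(data.frame(div = x, genotype = "a", resp = y), "resp")
    pr <- predict(fit, seq(6, 40, by = 1))
    mean(log(pr$hi) - log(pr$lo))
  }, numeric(1))
  expect_true(all(diff(width) < 0))
})
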