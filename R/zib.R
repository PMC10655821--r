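## Gauss-Hermite nodes/weights (physicists' convention, weight exp(-x^2))
## via the Golub-Welsch eigendecomposition of the Jacobi matrix
gauss_hermite <- function(n) {
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = e$vectors[1, ]^2 * sqrt(pi))
}

zib_design <- function(data, zero_on_div = TRUE) {
  g <- data$group
  if (is.factor(g) || is.character(g)) g <- as.numeric(factor(g)) - 1
  list(Xmean = cbind(1, g, data$div, g * data$div),
       Xzero = if (zero_on_div) cbind(1, data$div)
               else matrix(1, nrow(data), 1),
       y = data$response,
       batch = as.integer(factor(data$batch)))
}

#' Zero-inflated beta log-likelihood
#'
#' Each observation contributes `log pi` when the response is exactly zero
#' and `log(1 - pi) + log Beta(y; mu phi, (1 - mu) phi)` otherwise, with
#' `logit(pi)` linear in the zero-model covariates and `logit(mu)` linear in
#' the mean-model covariates (intercept, group, div, group x div), plus an
#' optional Gaussian batch random intercept in the mean model integrated out
#' by adaptive Gauss-Hermite quadrature (9 nodes per batch).
#'
#' @param beta mean-model coefficients (intercept, group, div, group x div).
#' @param phi beta precision (> 0).
#' @param gamma zero-model coefficients (intercept, and div when
#'   `zero_on_div`).
#' @param sigma_b batch random-intercept SD (0 disables the quadrature).
#' @param data data.frame with `response` in \[0, 1), `group`, `div`, `batch`.
#' @param zero_on_div condition the zero process on div.
#' @param nodes quadrature nodes per batch.
#' @return The log-likelihood (scalar).
#' @export
zib_loglik <- function(beta, phi, gamma, sigma_b = 0, data,
                       zero_on_div = TRUE, nodes = 9L) {
  stop_if_not(phi > 0, "precision phi must be > 0")
  d <- zib_design(data, zero_on_div)
  y <- d$y
  stop_if_not(all(y >= 0 & y < 1), "responses must lie in [0, 1)")
  eta_zero <- drop(d$Xzero %*% gamma)
  stop_if_not(all(is.finite(eta_zero)), "non-finite zero-model predictor")
  lp0 <- stats::plogis(eta_zero, log.p = TRUE)
  lp1 <- stats::plogis(-eta_zero, log.p = TRUE)   # log(1 - pi)
  pos <- y > 0
  eta_mean <- drop(d$Xmean %*% beta)
  ll <- sum(lp0[!pos]) + sum(lp1[pos])
  clamp_mu <- function(m) pmin(pmax(m, 1e-12), 1 - 1e-12)
  beta_part <- function(u, ix) {
    mu <- clamp_mu(stats::plogis(eta_mean[ix] + u))
    sum(stats::dbeta(y[ix], mu * phi, (1 - mu) * phi, log = TRUE))
  }
  if (sigma_b <= 0) {
    ix <- which(pos)
    if (length(ix)) ll <- ll + beta_part(0, ix)
    return(ll)
  }
  gh <- gauss_hermite(nodes)
  for (b in unique(d$batch)) {
    ix <- which(pos & d$batch == b)
    if (!length(ix)) next
    yb <- y[ix]
    eb <- eta_mean[ix]
    lo_y <- stats::qlogis(yb)
    h <- function(u) beta_part(u, ix) + stats::dnorm(u, 0, sigma_b, log = TRUE)
    ## Newton search for the conditional mode using analytic derivatives
    m <- 0
    for (it in 1:30) {
      mu <- clamp_mu(stats::plogis(eb + m))
      v <- mu * (1 - mu)
      g1 <- sum(phi * (lo_y - digamma(mu * phi) + digamma((1 - mu) * phi)) * v) -
        m / sigma_b^2
      g2 <- sum(phi * ((lo_y - digamma(mu * phi) + digamma((1 - mu) * phi)) *
                         (1 - 2 * mu) -
                         phi * (trigamma(mu * phi) + trigamma((1 - mu) * phi)) * v) *
                  v) - 1 / sigma_b^2
      if (!is.finite(g1) || !is.finite(g2) || g2 >= 0) break
      step <- g1 / g2
      m <- m - step
      if (abs(step) < 1e-10) break
    }
    if (!is.finite(m) || abs(m) > 10 * sigma_b + 10) {
      opt <- stats::optimize(h, interval = c(-5 * sigma_b - 3, 5 * sigma_b + 3),
                             maximum = TRUE, tol = 1e-8)
      m <- opt$maximum
    }
    mu <- clamp_mu(stats::plogis(eb + m))
    v <- mu * (1 - mu)
    h2 <- sum(phi * ((lo_y - digamma(mu * phi) + digamma((1 - mu) * phi)) *
                       (1 - 2 * mu) -
                       phi * (trigamma(mu * phi) + trigamma((1 - mu) * phi)) * v) *
                v) - 1 / sigma_b^2
    s_hat <- if (is.finite(h2) && h2 < 0) 1 / sqrt(-h2) else sigma_b
    u_j <- m + sqrt(2) * s_hat * gh$nodes
    lv <- vapply(u_j, h, numeric(1)) + gh$nodes^2 + log(gh$weights)
    M <- max(lv)
    ll <- ll + log(sqrt(2) * s_hat) + M + log(sum(exp(lv - M)))
  }
  ll
}

#' Fit the zero-inflated beta regression model
#'
#' Maximum likelihood via quasi-Newton (L-BFGS-B) optimization of
#' [zib_loglik()], with the precision and random-intercept SD on the log
#' scale, three starting points, and standard errors from the inverse
#' observed information. The zero-model intercept is bounded below at -20
#' (no-zeros data would otherwise push it to -Inf).
#'
#' @param data data.frame with `response` in \[0, 1), `group`, `div`,
#'   `batch`; responses equal to exactly 1 are clipped to 1 - 1e-6 with a
#'   warning.
#' @param with_random_intercept include the batch random intercept.
#' @param zero_on_div condition the zero probability on div.
#' @param nodes quadrature nodes per batch.
#' @param max_iter optimizer iteration cap.
#' @return Object of class `zib_fit`.
#' @export
fit_zib <- function(data, with_random_intercept = FALSE, zero_on_div = TRUE,
                    nodes = 9L, max_iter = 500L) {
  if (any(data$response >= 1)) {
    warning("responses equal to 1 clipped to 1 - 1e-6", call. = FALSE)
    data$response <- pmin(data$response, 1 - 1e-6)
  }
  d <- zib_design(data, zero_on_div)
  p_mean <- ncol(d$Xmean)
  p_zero <- ncol(d$Xzero)
  ## heuristic starts: logit-scale least squares for the mean model,
  ## logistic regression for the zero model
  pos <- d$y > 0
  yc <- pmin(pmax(d$y, 1e-4), 1 - 1e-4)
  b0 <- tryCatch(stats::lm.fit(d$Xmean[pos, , drop = FALSE],
                               stats::qlogis(yc[pos]))$coefficients,
                 error = function(e) rep(0, p_mean))
  b0[is.na(b0)] <- 0
  g0 <- tryCatch(stats::glm.fit(d$Xzero, as.numeric(!pos),
                                family = stats::binomial())$coefficients,
                 error = function(e) rep(0, p_zero))
  g0[is.na(g0)] <- 0
  g0 <- pmin(pmax(g0, -19), 19)
  base_par <- c(b0, log(5), g0, if (with_random_intercept) log(0.3))
  np <- length(base_par)
  unpack <- function(par) {
    par <- unname(par)
    list(beta = par[seq_len(p_mean)],
         phi = exp(par[p_mean + 1]),
         gamma = par[p_mean + 1 + seq_len(p_zero)],
         sigma_b = if (with_random_intercept) exp(par[np]) else 0)
  }
  negll <- function(par) {
    p <- unpack(par)
    v <- tryCatch(
      suppressWarnings(
        -zib_loglik(p$beta, p$phi, p$gamma, p$sigma_b, data,
                    zero_on_div = zero_on_div, nodes = nodes)),
      error = function(e) Inf)
    if (!is.finite(v)) 1e10 else v
  }
  ## analytic score for the separable (no random intercept) likelihood
  grad <- NULL
  if (!with_random_intercept) {
    z0 <- as.numeric(!pos)
    lo_y <- rep(0, length(d$y)); lo_y[pos] <- stats::qlogis(d$y[pos])
    l1y <- rep(0, length(d$y)); l1y[pos] <- log(1 - d$y[pos])
    ly <- rep(0, length(d$y)); ly[pos] <- log(d$y[pos])
    grad <- function(par) {
      p <- unpack(par)
      phi <- p$phi
      eta_m <- drop(d$Xmean %*% p$beta)
      mu <- pmin(pmax(stats::plogis(eta_m), 1e-12), 1 - 1e-12)
      pi0 <- stats::plogis(drop(d$Xzero %*% p$gamma))
      r <- phi * (lo_y - digamma(mu * phi) + digamma((1 - mu) * phi)) *
        mu * (1 - mu)
      r[!pos] <- 0
      g_beta <- -drop(crossprod(d$Xmean, r))
      dphi <- digamma(phi) - mu * digamma(mu * phi) -
        (1 - mu) * digamma((1 - mu) * phi) + mu * ly + (1 - mu) * l1y
      dphi[!pos] <- 0
      g_logphi <- -phi * sum(dphi)
      g_gamma <- -drop(crossprod(d$Xzero, z0 - pi0))
      out <- c(g_beta, g_logphi, g_gamma)
      if (any(!is.finite(out))) out[] <- 0
      out
    }
  }
  lower <- c(rep(-30, p_mean), -8, rep(-20, p_zero),
             if (with_random_intercept) -8)
  upper <- c(rep(30, p_mean), 10, rep(20, p_zero),
             if (with_random_intercept) 3)
  starts <- list(base_par,
                 base_par + rep(0.3, np) * rep_len(c(1, -1), np),
                 base_par * 0.5 - 0.1)
  best <- NULL
  for (s in starts) {
    o <- tryCatch(stats::optim(s, negll, gr = grad, method = "L-BFGS-B",
                               lower = lower, upper = upper,
                               control = list(maxit = max_iter, factr = 1e8)),
                  error = function(e) NULL)
    if (is.null(o)) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  stop_if_not(!is.null(best), "all optimizer starts failed")
  if (best$convergence != 0) {
    warning(sprintf("optimizer did not flag convergence (code %d): %s",
                    best$convergence, best$message %||% ""), call. = FALSE)
  }
  p <- unpack(best$par)
  H <- tryCatch(stats::optimHess(best$par, negll), error = function(e) NULL)
  vcov <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL)
          else NULL
  if (is.null(vcov) || any(!is.finite(vcov)) || any(diag(vcov) < 0)) {
    warning("observed information singular; standard errors suppressed",
            call. = FALSE)
    vcov <- NULL
  }
  se <- if (!is.null(vcov)) sqrt(diag(vcov)) else rep(NA_real_, np)
  names(best$par) <- names(se) <-
    c(paste0("beta.", c("(Intercept)", "group", "div", "group:div")[seq_len(p_mean)]),
      "log_phi",
      paste0("gamma.", c("(Intercept)", "div")[seq_len(p_zero)]),
      if (with_random_intercept) "log_sigma_b")
  structure(list(par = best$par, beta = p$beta, phi = p$phi, gamma = p$gamma,
                 sigma_b = p$sigma_b, se = se, vcov = vcov,
                 logLik = -best$value, df = np, n = nrow(data),
                 convergence = best$convergence,
                 zero_on_div = zero_on_div,
                 with_random_intercept = with_random_intercept),
            class = "zib_fit")
}

#' @export
print.zib_fit <- function(x, ...) {
  cat(sprintf("<zib_fit> n = %d, logLik = %.3f, phi = %.3f, sigma_b = %.3f\n",
              x$n, x$logLik, x$phi, x$sigma_b))
  est <- cbind(estimate = x$par, se = x$se)
  print(round(est, 4))
  invisible(x)
}

#' Likelihood-ratio test for the zero process
#'
#' Compares a fit whose zero probability is constant against one whose zero
#' probability depends on div. The statistic is twice the log-likelihood
#' difference, referred to a chi-square with the parameter-count difference.
#'
#' @param fit_null the restricted fit (zero model: intercept only).
#' @param fit_alt the full fit (zero model: intercept + div).
#' @return data.frame with `statistic`, `df`, `p_value`.
#' @export
lrt_zero_process <- function(fit_null, fit_alt) {
  stop_if_not(inherits(fit_null, "zib_fit") && inherits(fit_alt, "zib_fit"),
              "both arguments must be zib_fit objects")
  stop_if_not(fit_alt$df > fit_null$df && !fit_null$zero_on_div &&
                fit_alt$zero_on_div && fit_null$n == fit_alt$n,
              "fit_null must be nested in fit_alt (zero model intercept-only vs + div)")
  stat <- 2 * (fit_alt$logLik - fit_null$logLik)
  if (stat < -1e-4) {
    stop("alternative fit has lower likelihood than the null; refit needed")
  }
  stat <- max(stat, 0)
  df <- fit_alt$df - fit_null$df
  data.frame(statistic = stat, df = df,
             p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}
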