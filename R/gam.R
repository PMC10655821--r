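#' Configuration for the trajectory GAM
#'
#' The longitudinal model smooths each well feature over DIV with a cubic
#' regression spline carrying a shrinkage penalty: the usual second-derivative
#' penalty plus a small multiple (`eps`) of a penalty on the null space
#' (linear functions), so that as the smoothing parameter grows the smooth
#' shrinks all the way to zero rather than to a line. Residuals are
#' gamma-distributed with a log link; each genotype gets its own smooth plus
#' a genotype intercept. The smoothing parameter is chosen by GCV on a
#' log-spaced grid unless fixed.
#'
#' @param k basis dimension (>= 4).
#' @param eps shrinkage weight on the penalty null space (relative to the
#'   penalty's largest eigenvalue).
#' @param family `"gamma"` (log link) or `"gaussian"` (identity link).
#' @param lambda fixed smoothing parameter; `NULL` selects by GCV.
#' @param lambda_grid GCV search grid (default 40 log-spaced points,
#'   1e-4 to 1e6).
#' @param by_genotype fit a separate smooth per genotype (default; single
#'   shared smooth when `FALSE` or when the data hold one genotype).
#' @param max_iter,tol IRLS iteration cap and relative deviance tolerance.
#' @export
gam_config <- function(k = 10, eps = 1e-3, family = c("gamma", "gaussian"),
                       lambda = NULL, lambda_grid = NULL, by_genotype = TRUE,
                       max_iter = 200L, tol = 1e-9) {
  stop_if_not(k >= 4, "basis dimension k must be >= 4")
  stop_if_not(is.null(lambda) || lambda >= 0, "lambda must be >= 0")
  structure(list(k = as.integer(k), eps = eps, family = match.arg(family),
                 lambda = lambda,
                 lambda_grid = lambda_grid %||% 10^seq(-4, 6, length.out = 40),
                 by_genotype = by_genotype, max_iter = max_iter, tol = tol),
            class = "gam_config")
}

#' Cubic regression spline basis with shrinkage penalty
#'
#' Builds the natural cubic regression spline basis on `k` knots placed at
#' quantiles of the observed days, together with its second-derivative
#' penalty, augmented by `eps` times an identity on the penalty null space
#' so the penalized fit can shrink to zero.
#'
#' @param div_values covariate values (days); at least 4 distinct values.
#' @param k number of knots / basis functions.
#' @param eps shrinkage weight (relative to the largest penalty eigenvalue).
#' @return list with `X` (design at `div_values`), `S` (shrinkage-augmented
#'   penalty), `S_raw` (pure second-derivative penalty) and `knots`.
#' @export
build_spline_basis <- function(div_values, k = 10, eps = 1e-3) {
  ux <- sort(unique(div_values))
  stop_if_not(length(ux) >= 4, "need at least 4 distinct DIV values")
  k <- min(k, length(ux))
  knots <- as.numeric(stats::quantile(ux, probs = seq(0, 1, length.out = k),
                                      type = 7))
  stop_if_not(!any(duplicated(knots)), "degenerate (duplicated) knots")
  pen <- cr_penalty(knots)
  S_raw <- pen$S
  ev <- eigen(S_raw, symmetric = TRUE)
  null_ix <- which(ev$values < max(ev$values) * 1e-10)
  U0 <- ev$vectors[, null_ix, drop = FALSE]
  S <- S_raw + eps * max(ev$values) * tcrossprod(U0)
  list(X = cr_design(div_values, knots, pen$Fpad), S = S, S_raw = S_raw,
       knots = knots, Fpad = pen$Fpad)
}

## banded matrices of the natural cubic spline second-derivative penalty
cr_penalty <- function(knots) {
  k <- length(knots)
  h <- diff(knots)
  B <- matrix(0, k - 2, k - 2)
  D <- matrix(0, k - 2, k)
  for (i in seq_len(k - 2)) {
    B[i, i] <- (h[i] + h[i + 1]) / 3
    if (i < k - 2) B[i, i + 1] <- B[i + 1, i] <- h[i + 1] / 6
    D[i, i] <- 1 / h[i]
    D[i, i + 1] <- -1 / h[i] - 1 / h[i + 1]
    D[i, i + 2] <- 1 / h[i + 1]
  }
  Fm <- solve(B, D)
  list(S = t(D) %*% Fm, Fpad = rbind(0, Fm, 0))
}

## evaluate the cardinal natural-spline basis at x (clamped to knot range)
cr_design <- function(x, knots, Fpad = NULL) {
  if (is.null(Fpad)) Fpad <- cr_penalty(knots)$Fpad
  k <- length(knots)
  x <- pmin(pmax(x, knots[1]), knots[k])
  j <- pmin(pmax(findInterval(x, knots, rightmost.closed = TRUE), 1L), k - 1L)
  h <- knots[j + 1] - knots[j]
  am <- (knots[j + 1] - x) / h
  ap <- (x - knots[j]) / h
  cm <- ((knots[j + 1] - x)^3 / h - h * (knots[j + 1] - x)) / 6
  cp <- ((x - knots[j])^3 / h - h * (x - knots[j])) / 6
  X <- matrix(0, length(x), k)
  for (i in seq_along(x)) {
    X[i, j[i]] <- X[i, j[i]] + am[i]
    X[i, j[i] + 1] <- X[i, j[i] + 1] + ap[i]
    X[i, ] <- X[i, ] + cm[i] * Fpad[j[i], ] + cp[i] * Fpad[j[i] + 1, ]
  }
  X
}

## model matrix for the by-genotype smooth design; `basis` centred via Z
gam_design <- function(div, genotype, knots, Fpad, Z, levels) {
  X0 <- cr_design(div, knots, Fpad)
  Xs <- X0 %*% Z
  n <- length(div)
  G <- length(levels)
  cols <- list(matrix(1, n, 1))
  if (G > 1) {
    for (lev in levels[-1]) cols <- c(cols, list(matrix(genotype == lev, n, 1)))
  }
  for (lev in levels) cols <- c(cols, list(Xs * (genotype == lev)))
  do.call(cbind, cols)
}

## penalized IRLS for gamma(log) / gaussian(identity); unit IRLS weights in
## both cases, so each step is a penalized least squares solve
pirls <- function(y, X, Spen, family, max_iter = 200L, tol = 1e-9) {
  n <- length(y)
  XtX <- crossprod(X)
  A <- XtX + Spen
  if (family == "gaussian") {
    beta <- solve(A, crossprod(X, y))
    mu <- drop(X %*% beta)
    dev <- sum((y - mu)^2)
    iter <- 1L
  } else {
    mu <- (y + mean(y)) / 2
    eta <- log(mu)
    dev <- Inf
    for (iter in seq_len(max_iter)) {
      z <- eta + (y - mu) / mu
      beta <- solve(A, crossprod(X, z))
      eta <- pmin(pmax(drop(X %*% beta), -30), 30)
      mu <- exp(eta)
      dev_new <- 2 * sum(-log(y / mu) + (y - mu) / mu)
      if (is.finite(dev) && abs(dev - dev_new) < tol * (abs(dev_new) + 0.1)) {
        dev <- dev_new
        break
      }
      dev <- dev_new
    }
    if (iter == max_iter) {
      warning(sprintf("IRLS reached %d iterations (deviance %.6g)",
                      max_iter, dev), call. = FALSE)
    }
  }
  edf <- sum(diag(solve(A, XtX)))
  list(beta = drop(beta), mu = mu, dev = dev, edf = edf, A = A, iter = iter)
}

#' Fit the penalized-spline gamma GAM to a feature trajectory
#'
#' Smooths the named well feature over DIV with a shrinkage cubic regression
#' spline per genotype (plus genotype intercepts), assuming gamma-distributed
#' residuals with a log link, fitted by penalized IRLS. The smoothing
#' parameter is selected by GCV; dispersion uses the Pearson estimator; the
#' coefficient covariance is the penalized-information inverse scaled by the
#' dispersion. Zero or missing responses are dropped (the gamma family
#' excludes zeros; a well-day with no events carries no trajectory
#' information under the active-well inclusion rule).
#'
#' @param features WellFeatures table from [mea_features()] (or any
#'   data.frame with `div`, `genotype` and the feature column).
#' @param feature response column name.
#' @param config a [gam_config()].
#' @return Object of class `trajectory_fit`.
#' @export
fit_gamma_gam <- function(features, feature, config = gam_config()) {
  stop_if_not(feature %in% names(features),
              sprintf("unknown feature '%s'", feature))
  y <- features[[feature]]
  x <- features$div
  g <- as.character(features$genotype)
  keep <- !is.na(y) & !is.na(x)
  if (config$family == "gamma") {
    n_zero <- sum(y[keep] <= 0)
    if (n_zero > 0) {
      message(sprintf("dropping %d non-positive response values (gamma family)",
                      n_zero))
      keep <- keep & y > 0
    }
  }
  y <- y[keep]; x <- x[keep]; g <- g[keep]
  levels <- sort(unique(g))
  if (!config$by_genotype) {
    g <- rep("all", length(g)); levels <- "all"
  }
  basis <- build_spline_basis(x, k = config$k, eps = config$eps)
  k <- length(basis$knots)
  cmean <- colMeans(basis$X)
  Z <- qr.Q(qr(matrix(cmean, k, 1)), complete = TRUE)[, -1, drop = FALSE]
  Ss <- t(Z) %*% basis$S %*% Z
  X <- gam_design(x, g, basis$knots, basis$Fpad, Z, levels)
  p_par <- length(levels)              # intercept + genotype contrasts
  p_sm <- ncol(Z)
  pen_template <- matrix(0, ncol(X), ncol(X))
  for (gi in seq_along(levels)) {
    ix <- p_par + (gi - 1) * p_sm + seq_len(p_sm)
    pen_template[ix, ix] <- Ss
  }
  fit_at <- function(lam) pirls(y, X, lam * pen_template, config$family,
                                config$max_iter, config$tol)
  n <- length(y)
  if (is.null(config$lambda)) {
    gcv <- vapply(config$lambda_grid, function(lam) {
      f <- fit_at(lam)
      n * f$dev / (n - f$edf)^2
    }, numeric(1))
    lambda <- config$lambda_grid[which.min(gcv)]
  } else {
    lambda <- config$lambda
    gcv <- NULL
  }
  f <- fit_at(lambda)
  phi <- if (config$family == "gaussian") {
    f$dev / (n - f$edf)
  } else {
    sum(((y - f$mu) / f$mu)^2) / (n - f$edf)
  }
  Vb <- solve(f$A) * phi
  structure(list(coefficients = f$beta, Vb = Vb, lambda = lambda,
                 edf = f$edf, dispersion = phi, deviance = f$dev,
                 family = config$family, knots = basis$knots,
                 Fpad = basis$Fpad, Z = Z, levels = levels,
                 div_range = range(x), n = n, fitted = f$mu,
                 gcv = gcv, config = config,
                 data = data.frame(div = x, genotype = g, y = y)),
            class = "trajectory_fit")
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat(sprintf(paste0("<trajectory_fit> %s family, %d obs, genotypes: %s\n",
                     "  lambda = %.4g, edf = %.2f, dispersion = %.4g\n"),
              x$family, x$n, paste(x$levels, collapse = ", "),
              x$lambda, x$edf, x$dispersion))
  invisible(x)
}

#' Fitted trajectory with pointwise 95% confidence bands
#'
#' @param object a `trajectory_fit`.
#' @param div grid of days (defaults to the fitted range, step 1).
#' @param ... unused.
#' @return data.frame with `div`, `genotype`, `fit`, `lo`, `hi` on the
#'   response scale.
#' @export
predict.trajectory_fit <- function(object, div = NULL, ...) {
  div <- div %||% seq(object$div_range[1], object$div_range[2])
  rows <- lapply(object$levels, function(lev) {
    Xp <- gam_design(div, rep(lev, length(div)), object$knots, object$Fpad,
                     object$Z, object$levels)
    eta <- drop(Xp %*% object$coefficients)
    se <- sqrt(pmax(rowSums((Xp %*% object$Vb) * Xp), 0))
    if (object$family == "gamma") {
      data.frame(div = div, genotype = lev, fit = exp(eta),
                 lo = exp(eta - 1.96 * se), hi = exp(eta + 1.96 * se))
    } else {
      data.frame(div = div, genotype = lev, fit = eta,
                 lo = eta - 1.96 * se, hi = eta + 1.96 * se)
    }
  })
  do.call(rbind, rows)
}

#' Genotype difference curve with significance flags
#'
#' Link-scale difference between the two genotypes' fitted trajectories
#' (second level minus first), with pointwise 95% confidence interval from
#' the joint coefficient covariance, flagging days where the interval
#' excludes zero. Days outside the fitted range are refused.
#'
#' @param fit a `trajectory_fit` containing two genotypes.
#' @param div grid of days.
#' @return data.frame with `div`, `diff`, `se`, `lo`, `hi`, `significant`.
#' @export
genotype_difference <- function(fit, div = NULL) {
  stop_if_not(length(fit$levels) == 2,
              "fit must contain exactly two genotypes")
  div <- div %||% seq(fit$div_range[1], fit$div_range[2])
  stop_if_not(all(div >= fit$div_range[1] & div <= fit$div_range[2]),
              "extrapolation outside the fitted DIV range is refused")
  X1 <- gam_design(div, rep(fit$levels[1], length(div)), fit$knots, fit$Fpad,
                   fit$Z, fit$levels)
  X2 <- gam_design(div, rep(fit$levels[2], length(div)), fit$knots, fit$Fpad,
                   fit$Z, fit$levels)
  L <- X2 - X1
  d <- drop(L %*% fit$coefficients)
  se <- sqrt(pmax(rowSums((L %*% fit$Vb) * L), 0))
  lo <- d - 1.96 * se
  hi <- d + 1.96 * se
  data.frame(div = div, diff = d, se = se, lo = lo, hi = hi,
             significant = lo > 0 | hi < 0)
}
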