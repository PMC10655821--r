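#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

## truncated normal by rejection; bounds assumed well inside the bulk
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower | out[bad] > upper]
  }
  out
}

stop_if_not <- function(cond, msg, call. = FALSE) {
  if (!isTRUE(cond)) stop(msg, call. = call.)
}

## piecewise-linear interpolation over anchor (div, value) pairs with
## constant extrapolation; a single anchor gives a constant trajectory
interp_anchor <- function(div, value, at) {
  if (length(div) == 1L) return(rep(value, length(at)))
  stats::approx(div, value, xout = at, rule = 2)$y
}

## derive a stream of reproducible sub-seeds from one master seed,
## keeping everything under 2^31
derive_seeds <- function(seed, n, salt = 0L) {
  (as.integer(seed) + salt + 1000003L * seq_len(n)) %% 2147483629L
}
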