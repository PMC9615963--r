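# Fractional Gaussian noise and long-memory fire-count series.

# Exact fGn autocovariance gamma(k) = 0.5 (|k+1|^2H - 2|k|^2H + |k-1|^2H)
fgn_autocov <- function(hurst, lags) {
  h2 <- 2 * hurst
  0.5 * (abs(lags + 1)^h2 - 2 * abs(lags)^h2 + abs(lags - 1)^h2)
}

#' Generate fractional Gaussian noise by circulant embedding
#'
#' Simulates a stationary Gaussian series with the exact second-order
#' structure of fractional Gaussian noise (fGn) of Hurst exponent `hurst`,
#' zero mean and unit variance, using circulant embedding of the fGn
#' autocovariance (the Davies-Harte construction). `hurst = 0.5` yields
#' white noise; `hurst > 0.5` yields long-range persistent series, the
#' calibration inputs for the DFA estimator.
#'
#' @param hurst Target Hurst exponent, strictly inside (0, 1).
#' @param n Series length; a power of two, at least 64 (the circulant
#'   embedding is cheapest and provably nonnegative-definite there).
#' @param seed Integer seed; fixed seed gives an identical series.
#' @return Numeric vector of length `n`.
#' @examples
#' x <- gen_fgn(0.8, 256, seed = 1)
#' @export
gen_fgn <- function(hurst, n, seed) {
  if (!is_scalar_number(hurst) || hurst <= 0 || hurst >= 1) {
    stop("`hurst` must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (!is_scalar_number(n) || n < 64 || bitwAnd(as.integer(n), as.integer(n) - 1L) != 0L) {
    stop("`n` must be a power of two >= 64", call. = FALSE)
  }
  n <- as.integer(n)
  m <- 2L * n
  gam <- fgn_autocov(hurst, 0:n)
  circ <- c(gam, rev(gam[2:n]))          # length 2n, circulant first row
  lambda <- Re(stats::fft(circ))
  if (any(lambda < -1e-8 * max(lambda))) {
    stop(
      "circulant embedding produced negative spectral mass; ",
      "fall back to an autoregressive-cascade construction",
      call. = FALSE
    )
  }
  lambda <- pmax(lambda, 0)
  with_seed(seed, {
    v0 <- stats::rnorm(1)
    vn <- stats::rnorm(1)
    v1 <- stats::rnorm(n - 1L)
    v2 <- stats::rnorm(n - 1L)
    w <- complex(length.out = m)
    w[1L] <- sqrt(lambda[1L] / m) * v0
    w[n + 1L] <- sqrt(lambda[n + 1L] / m) * vn
    idx <- 2:n
    half <- sqrt(lambda[idx] / (2 * m))
    w[idx] <- half * complex(real = v1, imaginary = v2)
    w[m + 2L - idx] <- Conj(w[idx])
    Re(stats::fft(w))[seq_len(n)]
  })
}

#' Fire-count time series
#'
#' Container for an equidistant series of fire counts (or any real-valued
#' series destined for DFA). `values` are per-interval counts, `interval`
#' a calendar label such as `"month"`.
#'
#' @param values Numeric vector of per-interval values; finite.
#' @param interval Time-step label (default `"month"`).
#' @param start Start timestamp label.
#' @param label Series name.
#' @param hurst_true Optional generating Hurst exponent (ground truth).
#' @return An object of class `fire_series`.
#' @export
fire_series <- function(values, interval = "month", start = NA,
                        label = "series", hurst_true = NULL) {
  values <- as.numeric(values)
  if (length(values) == 0L || any(!is.finite(values))) {
    stop("`values` must be a non-empty finite numeric vector", call. = FALSE)
  }
  structure(
    list(values = values, interval = interval, start = start,
         label = label, hurst_true = hurst_true),
    class = "fire_series"
  )
}

#' @export
print.fire_series <- function(x, ...) {
  cat(sprintf(
    "<fire_series '%s'>  n = %d (%s), mean = %.2f, range = [%g, %g]\n",
    x$label, length(x$values), x$interval, mean(x$values),
    min(x$values), max(x$values)
  ))
  if (!is.null(x$hurst_true)) {
    cat(sprintf("  generating Hurst exponent: %.3f\n", x$hurst_true))
  }
  invisible(x)
}

#' @export
length.fire_series <- function(x) length(x$values)

#' Generate a long-memory fire-count series
#'
#' Draws nonnegative integer counts from a conditional Poisson whose
#' log-intensity is fractional Gaussian noise, so the count series inherits
#' the long memory of the latent process while staying a valid count
#' series. The latent Hurst exponent is recorded as ground truth.
#'
#' @param base_rate Expected counts per interval, > 0.
#' @param hurst Latent Hurst exponent in (0, 1).
#' @param n Series length (power of two, >= 64).
#' @param seed Integer seed.
#' @param sigma Log-intensity scale of the latent fGn (default 0.3; small
#'   enough that the mean stays near `base_rate`, large enough that the
#'   memory survives the count draw).
#' @param interval,label Passed to [fire_series()].
#' @return A [fire_series()] with integer counts and `hurst_true` set.
#' @export
gen_fire_series <- function(base_rate, hurst, n, seed, sigma = 0.3,
                            interval = "month", label = "synthetic") {
  if (!is_scalar_number(base_rate) || base_rate <= 0) {
    stop("`base_rate` must be > 0", call. = FALSE)
  }
  if (n < 64) stop("`n` < 64 is too short for multi-scale DFA", call. = FALSE)
  g <- gen_fgn(hurst, n, seed = split_seed(seed, 1L))
  lambda <- base_rate * exp(sigma * g - sigma^2 / 2)
  counts <- with_seed(split_seed(seed, 2L), stats::rpois(length(lambda), lambda))
  fire_series(counts, interval = interval, label = label, hurst_true = hurst)
}
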