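# Detrended fluctuation analysis (DFA-1) for fire-count series.
#
# The estimator follows the classic three-step construction: integrate the
# mean-centred series into a profile, remove an OLS linear trend inside
# non-overlapping boxes of size s, and read the scaling exponent alpha off
# the log-log regression of the root-mean-square fluctuation F(s) on s.
# alpha = 0.5 marks an uncorrelated series, alpha > 0.5 long-range
# persistence, alpha < 0.5 anti-persistence.

#' Integrated fire profile
#'
#' Cumulative sum of deviations from the series mean,
#' `X_t = sum_{i<=t} (x_i - <x>)`. By construction the final element is zero
#' up to rounding.
#'
#' @param series A [fire_series()] or numeric vector.
#' @return Numeric vector of the same length.
#' @export
compute_profile <- function(series) {
  x <- if (inherits(series, "fire_series")) series$values else as.numeric(series)
  if (length(x) < 2L) stop("series must have at least 2 observations", call. = FALSE)
  cumsum(x - mean(x))
}

#' Detrended fluctuation at one box size
#'
#' Splits the profile into non-overlapping boxes of size `s`, removes an
#' ordinary-least-squares linear trend inside each box, and returns the
#' root-mean-square residual over all covered points. Points in the tail
#' remainder (`N mod s`) are covered by a second pass of boxes anchored at
#' the end of the profile; the squared fluctuations of the two passes are
#' averaged.
#'
#' @param profile Numeric profile from [compute_profile()].
#' @param s Box size, `4 <= s <= N/4`.
#' @return Nonnegative scalar `F(s)`.
#' @export
fluctuation_function <- function(profile, s) {
  n <- length(profile)
  s <- as.integer(s)
  if (s < 4L || s > n %/% 4L) {
    stop(sprintf("box size s = %d outside [4, N/4] for N = %d", s, n),
         call. = FALSE)
  }
  f2 <- (box_mean_sq_resid(profile, s) +
           box_mean_sq_resid(rev(profile), s)) / 2
  sqrt(f2)
}

# Mean squared residual of per-box linear detrending, boxes anchored at the
# start; vectorised over boxes via closed-form OLS on t = 1..s.
box_mean_sq_resid <- function(profile, s) {
  nb <- length(profile) %/% s
  m <- matrix(profile[seq_len(nb * s)], nrow = s, ncol = nb)
  t0 <- seq_len(s) - (s + 1) / 2           # centred time index
  stt <- sum(t0^2)
  slope <- colSums(m * t0) / stt
  resid <- m - rep(colMeans(m), each = s) - outer(t0, slope)
  mean(resid^2)
}

# Default scale grid: log-spaced integer box sizes in [s_min, s_max],
# deduplicated.
dfa_scales <- function(s_min, s_max, n_scales) {
  unique(round(exp(seq(log(s_min), log(s_max), length.out = n_scales))))
}

#' Estimate the DFA scaling exponent
#'
#' Computes `F(s)` over a log-spaced grid of box sizes and fits the power
#' law `F(s) ~ s^alpha` by OLS on log-log axes. The returned object carries
#' the exponent, its slope standard error, the fit R^2 and all `(s, F(s))`
#' pairs.
#'
#' @param series A [fire_series()] or numeric vector, length >= `4 * s_min`.
#' @param s_min,s_max Smallest and largest box size (defaults 4 and `N/4`).
#' @param n_scales Number of log-spaced scales before deduplication
#'   (default 12, minimum 4).
#' @return An object of class `dfa_fit` with elements `alpha`, `alpha_se`,
#'   `r_squared`, `scales`, `fluctuations`, `n`.
#' @examples
#' x <- gen_fgn(0.5, 1024, seed = 1)
#' dfa_alpha(x)
#' @export
dfa_alpha <- function(series, s_min = 4L, s_max = NULL, n_scales = 12L) {
  x <- if (inherits(series, "fire_series")) series$values else as.numeric(series)
  n <- length(x)
  if (n_scales < 4L) stop("need at least 4 scales", call. = FALSE)
  if (is.null(s_max)) s_max <- n %/% 4L
  if (n < 4L * s_min) stop("series too short for the requested scales", call. = FALSE)
  prof <- compute_profile(x)
  scales <- dfa_scales(s_min, s_max, n_scales)
  fs <- vapply(scales, function(s) fluctuation_function(prof, s), numeric(1))
  keep <- fs > 0
  if (any(!keep)) {
    warning(sprintf("dropping %d scale(s) with F(s) = 0", sum(!keep)),
            call. = FALSE)
  }
  scales <- scales[keep]
  fs <- fs[keep]
  if (length(scales) < 4L) {
    stop("fewer than 4 usable scales after dropping degenerate ones",
         call. = FALSE)
  }
  fit <- stats::lm(log(fs) ~ log(scales))
  sm <- summary(fit)
  structure(
    list(
      alpha = unname(stats::coef(fit)[2L]),
      alpha_se = unname(sm$coefficients[2L, 2L]),
      r_squared = sm$r.squared,
      scales = scales,
      fluctuations = fs,
      n = n,
      label = if (inherits(series, "fire_series")) series$label else NULL
    ),
    class = "dfa_fit"
  )
}

#' @export
print.dfa_fit <- function(x, ...) {
  cat(sprintf(
    "DFA-1 fit%s: alpha = %.3f (SE %.3f), R^2 = %.4f, %d scales in [%d, %d], n = %d\n",
    if (is.null(x$label)) "" else sprintf(" '%s'", x$label),
    x$alpha, x$alpha_se, x$r_squared,
    length(x$scales), min(x$scales), max(x$scales), x$n
  ))
  cat(sprintf("  persistence: %s\n", classify_persistence(x)$label))
  invisible(x)
}

#' @export
coef.dfa_fit <- function(object, ...) c(alpha = object$alpha)

#' @export
plot.dfa_fit <- function(x, ...) {
  graphics::plot(log2(x$scales), log2(x$fluctuations),
                 xlab = "log2 box size s", ylab = "log2 F(s)",
                 main = sprintf("DFA-1: alpha = %.3f", x$alpha), ...)
  graphics::abline(stats::lm(log2(x$fluctuations) ~ log2(x$scales)), lty = 2)
  invisible(x)
}

#' Classify persistence from a DFA exponent
#'
#' @param result A `dfa_fit` object or a bare alpha value.
#' @param band Half-width of the "uncorrelated" band around 0.5
#'   (default 0: strict thresholding at 0.5).
#' @return List with `label` (one of `"anti-persistent"`, `"uncorrelated"`,
#'   `"persistent"`) and `alpha`.
#' @export
classify_persistence <- function(result, band = 0) {
  stopifnot(band >= 0)
  alpha <- if (inherits(result, "dfa_fit")) result$alpha else as.numeric(result)
  label <- if (alpha > 0.5 + band) {
    "persistent"
  } else if (alpha < 0.5 - band) {
    "anti-persistent"
  } else {
    "uncorrelated"
  }
  list(label = label, alpha = alpha)
}

#' Moving-window DFA exponents
#'
#' Re-estimates alpha over overlapping sub-windows of the series so that
#' the spread of the exponent (its SD across windows) can be reported as an
#' uncertainty alongside the whole-series slope standard error.
#'
#' @param series A [fire_series()] or numeric vector.
#' @param window Window length (default half the series, floor to a usable
#'   size).
#' @param step Offset between consecutive windows (default `window / 4`).
#' @param ... Passed to [dfa_alpha()].
#' @return Data frame with columns `start`, `alpha`.
#' @export
dfa_alpha_windows <- function(series, window = NULL, step = NULL, ...) {
  x <- if (inherits(series, "fire_series")) series$values else as.numeric(series)
  n <- length(x)
  window <- window %||% max(64L, n %/% 2L)
  step <- step %||% max(1L, window %/% 4L)
  starts <- seq(1L, n - window + 1L, by = step)
  alphas <- vapply(
    starts,
    function(i) dfa_alpha(x[i:(i + window - 1L)], ...)$alpha,
    numeric(1)
  )
  data.frame(start = starts, alpha = alphas)
}

#' Aggregate fire occurrences into count series
#'
#' Bins occurrence timestamps into a regular calendar interval, optionally
#' restricted to points inside one region mask, producing the
#' [fire_series()] that the DFA estimator consumes.
#'
#' @param occ An `occurrence_set` (see [read_occurrences()]).
#' @param interval `"month"` or `"year"`.
#' @param region Optional `region_mask` to restrict points spatially.
#' @param label Series label.
#' @return A [fire_series()] of counts, including empty intervals as zeros.
#' @export
aggregate_occurrences <- function(occ, interval = c("month", "year"),
                                  region = NULL, label = NULL) {
  interval <- match.arg(interval)
  pts <- occ$points
  if (!is.null(region)) {
    pts <- pts[points_in_region(pts$lon, pts$lat, region), , drop = FALSE]
  }
  if (nrow(pts) == 0L) stop("no occurrences to aggregate", call. = FALSE)
  d <- as.Date(pts$date)
  key <- if (interval == "month") format(d, "%Y-%m") else format(d, "%Y")
  rng <- range(d)
  all_keys <- if (interval == "month") {
    format(seq(rng[1], rng[2], by = "month"), "%Y-%m")
  } else {
    as.character(seq(as.integer(format(rng[1], "%Y")),
                     as.integer(format(rng[2], "%Y"))))
  }
  counts <- table(factor(key, levels = unique(c(all_keys, key))))
  fire_series(as.numeric(counts), interval = interval, start = all_keys[1L],
              label = label %||% (region$name %||% "all"))
}
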