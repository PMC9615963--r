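# Dry-season Regional Climate Change Index (RCCI) as a climate-hazard
# score: per-region percent changes of the bioclim variables, the regional
# warming amplification factor, the empirical n-binning and their sum.

#' Global mean warming by scenario and period
#'
#' Default global temperature changes used as the RWAF denominator:
#' 2.0 degC (SSP2-45, 2050), 2.7 degC (SSP2-45, 2090), 2.4 degC
#' (SSP5-85, 2050) and 4.4 degC (SSP5-85, 2090).
#'
#' @return Data frame `scenario`, `period`, `global_dt`.
#' @export
global_warming_table <- function() {
  data.frame(
    scenario = c("SSP2-45", "SSP2-45", "SSP5-85", "SSP5-85"),
    period = c("2050", "2090", "2050", "2090"),
    global_dt = c(2.0, 2.7, 2.4, 4.4)
  )
}

#' Zonal percent change between two layers
#'
#' Percent change of the regional mean, `100 * (mean_f - mean_p) / mean_p`
#' (zonal-mean-first; robust to near-zero cells). A `cellwise` method
#' (mean of cell ratios) is available for comparison.
#'
#' @param present,future Aligned [climate_layer()]s.
#' @param region A [region_mask()].
#' @param method `"zonal_mean"` (default) or `"cellwise"`.
#' @return Percent change (scalar).
#' @export
percent_change <- function(present, future, region,
                           method = c("zonal_mean", "cellwise")) {
  method <- match.arg(method)
  if (!same_grid(present, future)) stop("layers not aligned", call. = FALSE)
  idx <- region_cell_index(region, present)
  p <- present$values[idx]; f <- future$values[idx]
  ok <- is.finite(p) & is.finite(f)
  if (method == "cellwise") {
    if (any(p[ok] == 0)) stop("zero present cell value in region", call. = FALSE)
    return(100 * mean(f[ok] / p[ok] - 1))
  }
  mp <- mean(p[ok])
  if (!is.finite(mp) || mp == 0) {
    stop("region mean of the present layer is zero", call. = FALSE)
  }
  100 * (mean(f[ok]) - mp) / mp
}

#' Zonal absolute change between two layers
#'
#' Difference of regional means, `mean_f - mean_p` (e.g. the regional
#' temperature change in degC feeding the RWAF).
#'
#' @inheritParams percent_change
#' @return Scalar change in the layer's units.
#' @export
absolute_change <- function(present, future, region) {
  idx <- region_cell_index(region, present)
  p <- present$values[idx]; f <- future$values[idx]
  ok <- is.finite(p) & is.finite(f)
  mean(f[ok]) - mean(p[ok])
}

# Table of bin edges per factor kind; left-closed bins, so a value exactly
# on an edge falls in the higher bin (5 -> 1, 10 -> 2 for dP, ...).
N_FACTOR_BREAKS <- list(
  dP = c(5, 10, 15),
  dSigmaP = c(5, 10, 20),
  rwaf = c(1.1, 1.3, 1.5),
  dSigmaT = c(5, 10, 15)
)
N_FACTOR_VALUES <- c(0L, 1L, 2L, 4L)

#' Empirical n-factor of a climate-change magnitude
#'
#' Bins a factor value into the empirical weights {0, 1, 2, 4}. Percent
#' kinds (`dP`, `dSigmaP`, `dSigmaT`) are binned on the absolute value, so
#' a change of either sign scores; the RWAF is binned as-is. Bins are
#' left-closed: exactly 5 scores 1, exactly 10 scores 2 (for `dP`).
#'
#' Edges: `dP` and `dSigmaT` at (5, 10, 15); `dSigmaP` at (5, 10, 20);
#' `rwaf` at (1.1, 1.3, 1.5).
#'
#' @param kind One of `"dP"`, `"dSigmaP"`, `"rwaf"`, `"dSigmaT"`.
#' @param value Factor value(s); percent for the percent kinds,
#'   dimensionless for `rwaf`.
#' @return Integer n value(s) in {0, 1, 2, 4}.
#' @export
n_factor <- function(kind, value) {
  if (!kind %in% names(N_FACTOR_BREAKS)) {
    stop("unknown factor kind: ", kind, call. = FALSE)
  }
  if (any(!is.finite(value))) stop("factor value must be finite", call. = FALSE)
  v <- if (kind == "rwaf") value else abs(value)
  N_FACTOR_VALUES[findInterval(v, N_FACTOR_BREAKS[[kind]]) + 1L]
}

#' Regional warming amplification factor
#'
#' Relates the regional temperature change to the global mean change.
#' Ratio mode (default) returns `regional_dt / global_dt`, the scale on
#' which the binning edges (1.1, 1.3, 1.5) are defined; difference mode
#' returns `regional_dt - global_dt`.
#'
#' @param regional_dt Regional mean temperature change (degC).
#' @param global_dt Global mean temperature change (degC), > 0.
#' @param mode `"ratio"` (default) or `"difference"`.
#' @return RWAF value(s).
#' @export
rwaf <- function(regional_dt, global_dt, mode = c("ratio", "difference")) {
  mode <- match.arg(mode)
  stopifnot(all(global_dt > 0))
  if (mode == "ratio") regional_dt / global_dt else regional_dt - global_dt
}

#' Bundle hazard factors and their n values
#'
#' @param dP Percent change in annual precipitation.
#' @param dSigmaP Percent change in interannual precipitation variability.
#' @param rwaf_value Regional warming amplification factor.
#' @param dSigmaT Percent change in interannual temperature variability.
#' @return List of class `hazard_factors` carrying the raw values and the
#'   binned `n_dP`, `n_dSigmaP`, `n_rwaf`, `n_dSigmaT`.
#' @export
hazard_factors <- function(dP, dSigmaP, rwaf_value, dSigmaT) {
  vals <- list(dP = dP, dSigmaP = dSigmaP, rwaf = rwaf_value,
               dSigmaT = dSigmaT)
  if (any(vapply(vals, function(v) is.null(v) || !is.finite(v), logical(1)))) {
    stop("all four hazard factors must be present and finite", call. = FALSE)
  }
  structure(
    c(vals, list(
      n_dP = n_factor("dP", dP),
      n_dSigmaP = n_factor("dSigmaP", dSigmaP),
      n_rwaf = n_factor("rwaf", rwaf_value),
      n_dSigmaT = n_factor("dSigmaT", dSigmaT)
    )),
    class = "hazard_factors"
  )
}

#' Dry-season RCCI hazard score
#'
#' Binned mode (the index definition) sums the four empirical n values,
#' giving an integer in 0..16. The `raw_sum` variant sums the absolute
#' factor magnitudes `|dP| + |dSigmaP| + rwaf + |dSigmaT|` without binning,
#' retaining a continuous hazard scale.
#'
#' @param factors A [hazard_factors()] object.
#' @param mode `"binned"` (default) or `"raw_sum"`.
#' @return Scalar hazard value.
#' @export
rcci_ds <- function(factors, mode = c("binned", "raw_sum")) {
  mode <- match.arg(mode)
  stopifnot(inherits(factors, "hazard_factors"))
  if (mode == "binned") {
    factors$n_dP + factors$n_dSigmaP + factors$n_rwaf + factors$n_dSigmaT
  } else {
    abs(factors$dP) + abs(factors$dSigmaP) + factors$rwaf + abs(factors$dSigmaT)
  }
}

#' Per-region hazard table from climate stacks
#'
#' For every region and scenario/period: percent change in annual
#' precipitation (bio12) by [percent_change()], regional warming from the
#' bio1 means via [absolute_change()] turned into an RWAF against the
#' global warming table, interannual variability changes taken from the
#' supplied `variability` table, then n-binning and the RCCI sum.
#'
#' @param present Present [climate_stack()].
#' @param future Nested list `scenario -> period -> climate_stack`.
#' @param regions List of [region_mask()]s.
#' @param variability Data frame `region`, `scenario`, `period`,
#'   `dSigmaP`, `dSigmaT` (percent changes in interannual SDs); these are
#'   accepted as direct inputs because a climatological baseline carries no
#'   interannual series to derive them from.
#' @param warming Global warming table (default [global_warming_table()]).
#' @param rwaf_mode Passed to [rwaf()].
#' @param mode Passed to [rcci_ds()]; both variants are reported.
#' @return Data frame with one row per region x scenario x period:
#'   factor values, n values, `rcci_ds` (chosen mode) and `rcci_raw`.
#' @export
hazard_table <- function(present, future, regions, variability,
                         warming = global_warming_table(),
                         rwaf_mode = "ratio", mode = "binned") {
  rows <- list()
  for (scen in names(future)) {
    for (per in names(future[[scen]])) {
      fs <- future[[scen]][[per]]
      gdt <- warming$global_dt[warming$scenario == scen & warming$period == per]
      if (length(gdt) != 1L) {
        stop(sprintf("no global warming entry for %s / %s", scen, per),
             call. = FALSE)
      }
      for (r in regions) {
        vb <- variability[variability$region == r$name &
                            variability$scenario == scen &
                            variability$period == per, ]
        if (nrow(vb) != 1L) {
          stop(sprintf("missing variability entry for %s / %s / %s",
                       r$name, scen, per), call. = FALSE)
        }
        dP <- percent_change(present$bio12, fs$bio12, r)
        rdt <- absolute_change(present$bio1, fs$bio1, r)
        rw <- rwaf(rdt, gdt, mode = rwaf_mode)
        hf <- hazard_factors(dP, vb$dSigmaP, rw, vb$dSigmaT)
        rows[[length(rows) + 1L]] <- data.frame(
          region = r$name, nfdc_class = r$nfdc_class,
          scenario = scen, period = per,
          dP = dP, dSigmaP = vb$dSigmaP, regional_dt = rdt, rwaf = rw,
          dSigmaT = vb$dSigmaT,
          n_dP = hf$n_dP, n_dSigmaP = hf$n_dSigmaP, n_rwaf = hf$n_rwaf,
          n_dSigmaT = hf$n_dSigmaT,
          rcci_ds = rcci_ds(hf, mode = mode),
          rcci_raw = rcci_ds(hf, mode = "raw_sum")
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
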