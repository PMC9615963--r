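# Sensitivity -> resilience -> vulnerability -> climate risk arithmetic
# and the class-level (NFDC) summaries.

#' Zonal vegetation sensitivity
#'
#' Mean and SD of a vegetation-sensitivity (VSI-like) layer inside a
#' region mask, nodata excluded.
#'
#' @param vsi_layer A [climate_layer()] holding the sensitivity index.
#' @param region A [region_mask()].
#' @return List `mean`, `sd`, `n_cells` (SD is the population SD).
#' @export
zonal_sensitivity <- function(vsi_layer, region) {
  zonal_mean_sd(vsi_layer, region)
}

#' Resilience status of a region
#'
#' Arithmetic mean of the vegetation-loss fraction and the non-protected
#' area fraction; the lower the value, the greater the resilience.
#'
#' @param vegetation_loss,non_protected Fractions in [0, 1] (vectorised).
#' @return Resilience status in [0, 1].
#' @export
resilience_status <- function(vegetation_loss, non_protected) {
  if (any(vegetation_loss < 0 | vegetation_loss > 1 |
            non_protected < 0 | non_protected > 1)) {
    stop("inputs must be fractions in [0, 1]", call. = FALSE)
  }
  (vegetation_loss + non_protected) / 2
}

#' Relative weights over regions
#'
#' Excess of each region's value over the across-region minimum,
#' `delta_i = value_i - min(values)`; at least one delta is zero.
#'
#' @param values Numeric vector, length >= 2.
#' @return Numeric vector of nonnegative deltas.
#' @export
relative_weights <- function(values) {
  stopifnot(length(values) >= 2L)
  values - min(values)
}

#' Vulnerability index
#'
#' Arithmetic mean of the relative sensitivity weight (deltaS) and the
#' relative resilience weight (deltaR). The two deltas are combined on
#' their native scales (sensitivity-index units vs fractions) without
#' normalisation; set `normalise = TRUE` to rescale each delta vector to
#' [0, 1] first (a variant, not the published construction).
#'
#' @param deltaS,deltaR Nonnegative vectors of relative weights.
#' @param normalise Rescale each delta vector by its maximum first
#'   (default `FALSE`).
#' @return Vulnerability index vector.
#' @export
vulnerability_index <- function(deltaS, deltaR, normalise = FALSE) {
  if (any(deltaS < 0 | deltaR < 0)) {
    stop("relative weights must be nonnegative", call. = FALSE)
  }
  if (normalise) {
    if (max(deltaS) > 0) deltaS <- deltaS / max(deltaS)
    if (max(deltaR) > 0) deltaR <- deltaR / max(deltaR)
  }
  (deltaS + deltaR) / 2
}

#' Climate risk
#'
#' Product of the vulnerability index and the climate hazard (vectorised).
#'
#' @param vi Vulnerability index, >= 0.
#' @param hazard Hazard value(s).
#' @return Risk, unrounded (table builders round to 2 decimals for
#'   reporting).
#' @export
climate_risk <- function(vi, hazard) {
  if (any(vi < 0)) stop("vulnerability index must be >= 0", call. = FALSE)
  vi * hazard
}

#' Build the per-region vulnerability table
#'
#' Combines zonal sensitivity means with vegetation-loss / protection
#' fractions into resilience status, relative weights and the
#' vulnerability index.
#'
#' @param sensitivity Named numeric vector (or data frame column) of
#'   per-region sensitivity means.
#' @param inputs Data frame `region`, `nfdc_class`, `vegetation_loss`,
#'   `non_protected` (regions in the same order as `sensitivity`).
#' @return Data frame with `sensitivity`, `resilience`, `deltaS`,
#'   `deltaR`, `vi` per region.
#' @export
vulnerability_table <- function(sensitivity, inputs) {
  stopifnot(length(sensitivity) == nrow(inputs))
  res <- resilience_status(inputs$vegetation_loss, inputs$non_protected)
  dS <- relative_weights(as.numeric(sensitivity))
  dR <- relative_weights(res)
  data.frame(
    region = inputs$region, nfdc_class = inputs$nfdc_class,
    sensitivity = as.numeric(sensitivity),
    vegetation_loss = inputs$vegetation_loss,
    non_protected = inputs$non_protected,
    resilience = res, deltaS = dS, deltaR = dR,
    vi = vulnerability_index(dS, dR)
  )
}

#' Per-region climate-risk records
#'
#' Joins the vulnerability table with a hazard table and multiplies,
#' rounding the reported risk to 2 decimals (internal arithmetic is
#' unrounded).
#'
#' @param vulnerability Data frame from [vulnerability_table()] (needs
#'   `region`, `nfdc_class`, `vi`).
#' @param hazard Data frame with `region`, `scenario`, `period` and a
#'   hazard column (`rcci_ds` by default, or `hazard`).
#' @param hazard_col Name of the hazard column.
#' @return Data frame `region`, `nfdc_class`, `scenario`, `period`, `vi`,
#'   `hazard`, `risk`.
#' @export
risk_table <- function(vulnerability, hazard, hazard_col = NULL) {
  hazard_col <- hazard_col %||%
    intersect(c("rcci_ds", "hazard"), names(hazard))[1L]
  if (is.na(hazard_col)) stop("no hazard column found", call. = FALSE)
  m <- merge(hazard[, c("region", "scenario", "period", hazard_col)],
             vulnerability[, c("region", "nfdc_class", "vi")],
             by = "region")
  m$hazard <- m[[hazard_col]]
  m$risk <- round(climate_risk(m$vi, m$hazard), 2)
  out <- m[order(m$scenario, m$period, m$region),
           c("region", "nfdc_class", "scenario", "period", "vi", "hazard",
             "risk")]
  rownames(out) <- NULL
  out
}

#' Class-level risk summaries
#'
#' Mean and sample SD (n - 1 denominator) of the risk per fire-dependence
#' class, scenario and period; single-member groups report `NA` SD.
#'
#' @param records Data frame with `nfdc_class`, `scenario`, `period`,
#'   `risk` (e.g. from [risk_table()]).
#' @param by Grouping column (default `"nfdc_class"`).
#' @return Data frame `nfdc_class`, `scenario`, `period`, `n`, `mean`,
#'   `sd`.
#' @export
group_summary <- function(records, by = "nfdc_class") {
  stopifnot(nrow(records) >= 1L)
  key <- interaction(records[[by]], records$scenario, records$period,
                     drop = TRUE)
  out <- do.call(rbind, lapply(split(records, key), function(g) {
    data.frame(
      nfdc_class = g[[by]][1L], scenario = g$scenario[1L],
      period = g$period[1L], n = nrow(g),
      mean = mean(g$risk),
      sd = if (nrow(g) > 1L) stats::sd(g$risk) else NA_real_
    )
  }))
  rownames(out) <- NULL
  out[order(out$scenario, out$period, out$nfdc_class), ]
}

#' Reference hazard, resilience and vulnerability values for the Brazilian
#' biomes
#'
#' Per-biome climate hazards (four scenario/period combinations),
#' resilience status and vulnerability index as printed by a published
#' national fire-climate risk assessment of the six Brazilian biomes (with
#' the Atlantic Forest also split into NE/SE sub-regions). Shipped as a
#' plain-text table so the downstream risk arithmetic can be reproduced
#' from the printed values.
#'
#' @param long Return in long format (`region`, `nfdc_class`, `subregion`,
#'   `scenario`, `period`, `hazard`, `resilience`, `vi`)?
#' @return Data frame.
#' @export
reference_hazard_table <- function(long = FALSE) {
  path <- system.file("extdata", "brazil_biomes_hazard_vulnerability.csv",
                      package = "firerisk", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!long) return(df)
  cells <- expand.grid(scenario = c("SSP2-45", "SSP5-85"),
                       period = c("2050", "2090"),
                       stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    col <- sprintf("hazard_%s_%s", sub("-", "", tolower(cells$scenario[i])),
                   cells$period[i])
    data.frame(region = df$region, nfdc_class = df$nfdc_class,
               subregion = df$subregion, scenario = cells$scenario[i],
               period = cells$period[i], hazard = df[[col]],
               resilience = df$resilience, vi = df$vi)
  }))
  out[order(out$scenario, out$period, out$region), ]
}

#' Reference climate-risk values for the Brazilian biomes
#'
#' Printed per-biome climate risks of the same published assessment (see
#' [reference_hazard_table()]), used to verify the vulnerability x hazard
#' arithmetic and its class summaries.
#'
#' @param long Return long format (`region`, ..., `scenario`, `period`,
#'   `risk`)?
#' @return Data frame.
#' @export
reference_risk_table <- function(long = FALSE) {
  path <- system.file("extdata", "brazil_biomes_risk.csv",
                      package = "firerisk", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!long) return(df)
  cells <- expand.grid(scenario = c("SSP2-45", "SSP5-85"),
                       period = c("2050", "2090"),
                       stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    col <- sprintf("risk_%s_%s", sub("-", "", tolower(cells$scenario[i])),
                   cells$period[i])
    data.frame(region = df$region, nfdc_class = df$nfdc_class,
               subregion = df$subregion, scenario = cells$scenario[i],
               period = cells$period[i], risk = df[[col]])
  }))
  out[order(out$scenario, out$period, out$region), ]
}
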