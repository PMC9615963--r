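# Synthetic inputs with known ground truth: climate stacks with prescribed
# per-region percent changes, climate-driven fire points, region masks and
# per-region vulnerability inputs. Everything is a pure function of
# (config, seed) so that recovery tests have exact targets.

BIOCLIM_VARS <- c("bio1", "bio9", "bio12", "bio17")

#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator: grid geometry,
#' number of regions, target Hurst exponents for the per-region fire
#' series, per-region/per-variable percent changes of the future climate,
#' and the logistic coefficients of the generating fire-suitability
#' surface.
#'
#' @param seed Root seed; all generator randomness derives from it.
#' @param grid_shape `c(rows, cols)` of the analysis grid.
#' @param cell_size_deg Square cell size in degrees (default 0.1, roughly
#'   an 11-km cell, so the 10-km thinning rule bites).
#' @param origin `c(xll, yll)` lower-left corner in degrees.
#' @param n_regions Number of regions tiling the grid.
#' @param hurst_targets Target Hurst exponents in (0, 1), recycled over
#'   regions.
#' @param series_length Length of each fire-count series (power of two,
#'   >= 64; default 128, i.e. roughly a decade of monthly counts).
#' @param base_rate Mean fire counts per interval.
#' @param scenario_deltas Named list `scenario -> period -> matrix`
#'   (`n_regions` x 4 variables) of percent changes; default
#'   [default_scenario_deltas()].
#' @param suitability_coefficients Named vector: intercept plus one slope
#'   per bioclim variable, applied to z-standardised layers.
#' @param n_fire_points Number of synthetic fire occurrences.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       grid_shape = c(60L, 60L),
                       cell_size_deg = 0.1,
                       origin = c(-53, -22),
                       n_regions = 6L,
                       hurst_targets = c(0.65, 0.7, 0.75),
                       series_length = 128L,
                       base_rate = 120,
                       scenario_deltas = NULL,
                       suitability_coefficients = c(
                         intercept = -2.5, bio1 = 3, bio9 = 1,
                         bio12 = -6, bio17 = -2.5
                       ),
                       n_fire_points = 5000L) {
  cfg <- list(
    seed = as.integer(seed), grid_shape = as.integer(grid_shape),
    cell_size_deg = cell_size_deg, origin = origin,
    n_regions = as.integer(n_regions), hurst_targets = hurst_targets,
    series_length = as.integer(series_length), base_rate = base_rate,
    scenario_deltas = scenario_deltas %||% default_scenario_deltas(n_regions),
    suitability_coefficients = suitability_coefficients,
    n_fire_points = as.integer(n_fire_points)
  )
  if (any(cfg$hurst_targets <= 0 | cfg$hurst_targets >= 1)) {
    stop("hurst_targets must lie in (0, 1)", call. = FALSE)
  }
  if (cfg$series_length < 64L) stop("series_length must be >= 64", call. = FALSE)
  structure(cfg, class = "sim_config")
}

sim_grid <- function(config) {
  list(nrow = config$grid_shape[1], ncol = config$grid_shape[2],
       xll = config$origin[1], yll = config$origin[2],
       cellsize = config$cell_size_deg)
}

#' Default future-change matrix per scenario and period
#'
#' Prescribes per-region percent changes for the four bioclim variables
#' under two emission pathways and two horizons: warming grows from the
#' moderate to the high pathway and from mid to late century, annual and
#' dry-quarter precipitation mostly decline, and regions differ so that
#' zonal recovery tests can tell them apart.
#'
#' @param n_regions Number of regions.
#' @return Named list `scenario -> period -> matrix` with rownames
#'   `region_i` and colnames the four bioclim variables; entries are
#'   percent changes.
#' @export
default_scenario_deltas <- function(n_regions = 6L) {
  base <- list(
    "SSP2-45" = list("2050" = c(t = 6, p = -4), "2090" = c(t = 9, p = -7)),
    "SSP5-85" = list("2050" = c(t = 8, p = -6), "2090" = c(t = 16, p = -12))
  )
  spread <- seq(-2, 2, length.out = n_regions)  # region-to-region contrast
  lapply(base, function(periods) {
    lapply(periods, function(b) {
      m <- cbind(
        bio1 = b[["t"]] + spread,
        bio9 = b[["t"]] + spread + 1,
        bio12 = b[["p"]] - spread,
        bio17 = b[["p"]] - spread - 2
      )
      rownames(m) <- paste0("region_", seq_len(n_regions))
      m
    })
  })
}

# Smooth random field: sum of a few low-frequency sinusoids, unit-ish scale.
smooth_field <- function(nr, nc, seed, n_waves = 6L) {
  with_seed(seed, {
    x <- matrix(rep(seq(0, 1, length.out = nc), each = nr), nr, nc)
    y <- matrix(rep(seq(0, 1, length.out = nr), times = nc), nr, nc)
    f <- matrix(0, nr, nc)
    for (k in seq_len(n_waves)) {
      fx <- stats::runif(1, 0.5, 2.5); fy <- stats::runif(1, 0.5, 2.5)
      ph <- stats::runif(1, 0, 2 * pi); amp <- stats::rnorm(1, 0, 1 / k)
      f <- f + amp * sin(2 * pi * (fx * x + fy * y) + ph)
    }
    f / stats::sd(f)
  })
}

#' Generate the present-day climate stack
#'
#' Builds four smooth bioclim layers on the configured grid: annual mean
#' temperature (bio1, degC), driest-quarter temperature (bio9, degC),
#' annual precipitation (bio12, mm) and driest-quarter precipitation
#' (bio17, mm). Large-scale latitudinal/longitudinal gradients dominate,
#' with smooth random texture on top, so region means are well separated.
#'
#' @param config A [sim_config()].
#' @return A [climate_stack()] with layers `bio1`, `bio9`, `bio12`, `bio17`.
#' @export
gen_present_stack <- function(config) {
  g <- sim_grid(config)
  nr <- g$nrow; nc <- g$ncol
  lat_grad <- matrix(rep(seq(1, 0, length.out = nr), times = nc), nr, nc)
  lon_grad <- matrix(rep(seq(0, 1, length.out = nc), each = nr), nr, nc)
  s1 <- smooth_field(nr, nc, split_seed(config$seed, 11L))
  s2 <- smooth_field(nr, nc, split_seed(config$seed, 12L))
  s3 <- smooth_field(nr, nc, split_seed(config$seed, 13L))
  s4 <- smooth_field(nr, nc, split_seed(config$seed, 14L))
  # gradient-dominated fields with mild smooth texture; the dry-quarter
  # layers share only part of the annual signal so the four predictors stay
  # moderately (not perfectly) correlated
  bio1 <- 20 + 6 * lat_grad + 0.35 * s1
  bio9 <- 0.8 * bio1 + 6 + 0.7 * s2
  bio12 <- 900 + 1100 * lon_grad + 42 * s3
  bio17 <- pmax(0.06 * bio12 + 60 + 10.5 * s4, 5)  # arg order keeps dim attr
  mk <- function(v, nm) climate_layer(v, xll = g$xll, yll = g$yll,
                                      cellsize = g$cellsize, name = nm)
  climate_stack(list(bio1 = mk(bio1, "bio1"), bio9 = mk(bio9, "bio9"),
                     bio12 = mk(bio12, "bio12"), bio17 = mk(bio17, "bio17")))
}

#' Generate present and future climate stacks
#'
#' The future layer for each scenario/period scales present cell values
#' region by region so that the region-mean percent change equals the
#' prescribed delta exactly; nodata cells are preserved.
#'
#' @param config A [sim_config()].
#' @param regions Optional region list (default [gen_regions()] on the
#'   config grid).
#' @return List with elements `present` (a [climate_stack()]), `future`
#'   (nested list `scenario -> period -> climate_stack`), `regions`, and
#'   `deltas` (the generating truth).
#' @export
gen_climate_stack <- function(config, regions = NULL) {
  regions <- regions %||% gen_regions(sim_grid(config), config$n_regions)
  present <- gen_present_stack(config)
  future <- lapply(config$scenario_deltas, function(periods) {
    lapply(periods, function(delta) {
      if (nrow(delta) != length(regions)) {
        stop("scenario_deltas must cover every region", call. = FALSE)
      }
      if (any(delta[, c("bio12", "bio17")] <= -100)) {
        stop("precipitation change <= -100% would give negative rainfall",
             call. = FALSE)
      }
      layers <- lapply(BIOCLIM_VARS, function(v) {
        lay <- present[[v]]
        for (i in seq_along(regions)) {
          idx <- region_cell_index(regions[[i]], lay)
          lay$values[idx] <- lay$values[idx] * (1 + delta[i, v] / 100)
        }
        lay
      })
      names(layers) <- BIOCLIM_VARS
      climate_stack(layers)
    })
  })
  list(present = present, future = future, regions = regions,
       deltas = config$scenario_deltas)
}

#' Generate climate-driven fire occurrence points
#'
#' Samples `n` points with probability proportional to a logistic
#' suitability surface `plogis(b0 + sum(b_v * z_v))` where `z_v` are the
#' z-standardised bioclim layers, then jitters each point uniformly within
#' its cell and assigns a random date in the configured decade. The true
#' suitability layer and coefficients are returned as ground truth.
#'
#' @param stack A [climate_stack()] with the four bioclim layers.
#' @param coefficients Named vector `intercept` plus per-variable slopes.
#' @param n Number of points, >= 1.
#' @param seed Integer seed.
#' @param date_range Two dates bounding the simulated timestamps.
#' @return List with `occurrences` (an [occurrence_set()]),
#'   `suitability_truth` (a [climate_layer()] of generating probabilities)
#'   and `coefficients` / `standardisation` ground truth.
#' @export
gen_fire_points <- function(stack, coefficients, n, seed,
                            date_range = as.Date(c("2011-01-01", "2020-12-31"))) {
  stopifnot(n >= 1)
  ref <- stack[[1L]]
  vals <- sapply(stack, function(l) as.vector(l$values))
  mu <- colMeans(vals, na.rm = TRUE)
  sdev <- apply(vals, 2L, stats::sd, na.rm = TRUE)
  degenerate <- sdev < 1e-12
  if (any(degenerate) && any(coefficients[names(stack)[degenerate]] != 0)) {
    warning("constant layer(s) with nonzero slope; sampling is uniform there",
            call. = FALSE)
    sdev[degenerate] <- 1
  }
  z <- sweep(sweep(vals, 2L, mu), 2L, sdev, "/")
  eta <- coefficients[["intercept"]] +
    as.vector(z %*% coefficients[names(stack)])
  p <- stats::plogis(eta)
  p[!is.finite(p)] <- 0
  truth <- ref
  truth$values <- matrix(p, nrow(ref$values), ncol(ref$values))
  truth$name <- "suitability_truth"
  coords <- layer_coords(ref)
  pts <- with_seed(seed, {
    cell <- sample.int(length(p), n, replace = TRUE, prob = p)
    half <- ref$cellsize / 2
    data.frame(
      lon = coords$lon[cell] + stats::runif(n, -half, half),
      lat = coords$lat[cell] + stats::runif(n, -half, half),
      date = date_range[1] +
        round(stats::runif(n, 0, as.numeric(diff(date_range))))
    )
  })
  list(
    occurrences = occurrence_set(pts),
    suitability_truth = truth,
    coefficients = coefficients,
    standardisation = list(mean = mu, sd = sdev)
  )
}

#' Generate per-region fire-count series
#'
#' One long-memory count series per region, with target Hurst exponents
#' recycled over regions and recorded as ground truth.
#'
#' @param config A [sim_config()].
#' @param regions Region list (for names).
#' @return Named list of [fire_series()].
#' @export
gen_region_fire_series <- function(config, regions) {
  h <- rep_len(config$hurst_targets, length(regions))
  out <- lapply(seq_along(regions), function(i) {
    gen_fire_series(
      base_rate = config$base_rate, hurst = h[i], n = config$series_length,
      seed = split_seed(config$seed, 100L + i), label = regions[[i]]$name
    )
  })
  names(out) <- vapply(regions, `[[`, "", "name")
  out
}

#' Generate per-region vulnerability inputs
#'
#' A smooth synthetic vegetation-sensitivity layer (VSI-like index, scale
#' of tens) plus per-region vegetation-loss and non-protected-area
#' fractions in [0, 1].
#'
#' @param config A [sim_config()].
#' @param regions Region list.
#' @return List with `vsi` (a [climate_layer()]) and `inputs` (data frame
#'   `region`, `nfdc_class`, `vegetation_loss`, `non_protected`).
#' @export
gen_vulnerability_inputs <- function(config, regions) {
  g <- sim_grid(config)
  f <- smooth_field(g$nrow, g$ncol, split_seed(config$seed, 21L))
  vsi <- climate_layer(18 + 4 * f, xll = g$xll, yll = g$yll,
                       cellsize = g$cellsize, name = "vsi")
  fr <- with_seed(split_seed(config$seed, 22L), {
    data.frame(
      region = vapply(regions, `[[`, "", "name"),
      nfdc_class = vapply(regions, `[[`, "", "nfdc_class"),
      vegetation_loss = round(stats::runif(length(regions), 0.1, 0.8), 3),
      non_protected = round(stats::runif(length(regions), 0.5, 0.95), 3)
    )
  })
  list(vsi = vsi, inputs = fr)
}

#' Write an occurrence table as CSV
#'
#' Columns `lon`, `lat`, `date` (ISO-8601); provenance flag columns are
#' preserved if present.
#'
#' @param occ An [occurrence_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(occ$points, path, row.names = FALSE)
  invisible(path)
}

#' Read an occurrence CSV
#'
#' @param path CSV with columns `lon`, `lat`, `date`.
#' @return An [occurrence_set()].
#' @export
read_occurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  occurrence_set(df)
}
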