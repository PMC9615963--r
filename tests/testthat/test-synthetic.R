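# Synthetic climate stacks, regions and climate-driven fire points:
# every generator must be recoverable from its own ground truth.

test_that("future stacks hit the prescribed per-region percent changes", {
  cfg <- sim_config(seed = 3, grid_shape = c(24L, 24L))
  clim <- gen_climate_stack(cfg)
  for (scen in names(clim$deltas)) {
    for (per in names(clim$deltas[[scen]])) {
      target <- clim$deltas[[scen]][[per]]
      for (i in seq_along(clim$regions)) {
        for (v in c("bio1", "bio12")) {
          got <- percent_change(clim$present[[v]],
                                clim$future[[scen]][[per]][[v]],
                                clim$regions[[i]])
          expect_lt(abs(got - target[i, v]), 0.1)
        }
      }
    }
  }
})

test_that("zero deltas reproduce the present stack exactly", {
  zero <- lapply(default_scenario_deltas(6), function(p) {
    lapply(p, function(m) m * 0)
  })
  cfg <- sim_config(seed = 1, grid_shape = c(20L, 20L),
                    scenario_deltas = zero)
  clim <- gen_climate_stack(cfg)
  for (v in c("bio1", "bio9", "bio12", "bio17")) {
    expect_identical(clim$future[["SSP2-45"]][["2050"]][[v]]$values,
                     clim$present[[v]]$values)
  }
})

test_that("distinct region deltas stay distinct (brute-force zonal check)", {
  deltas <- default_scenario_deltas(2)
  deltas[["SSP2-45"]][["2050"]][, "bio1"] <- c(5, 15)
  cfg <- sim_config(seed = 2, grid_shape = c(20L, 20L), n_regions = 2L,
                    scenario_deltas = deltas)
  clim <- gen_climate_stack(cfg)
  fut <- clim$future[["SSP2-45"]][["2050"]]$bio1
  for (i in 1:2) {
    # brute-force over the explicit cell list, independent of the zonal path
    o_p <- oracle_zonal(clim$present$bio1, clim$regions[[i]])
    o_f <- oracle_zonal(fut, clim$regions[[i]])
    expect_equal(100 * (o_f$mean - o_p$mean) / o_p$mean, c(5, 15)[i],
                 tolerance = 1e-6)
  }
})

test_that("impossible precipitation deltas are rejected", {
  deltas <- default_scenario_deltas(6)
  deltas[["SSP5-85"]][["2090"]][2, "bio12"] <- -120
  cfg <- sim_config(seed = 1, grid_shape = c(20L, 20L),
                    scenario_deltas = deltas)
  expect_error(gen_climate_stack(cfg), "-100")
})

test_that("regions tile the grid disjointly with the NFDC composition", {
  g <- list(nrow = 60, ncol = 60, xll = -53, yll = -22, cellsize = 0.1)
  regions <- gen_regions(g, 6)
  cover <- matrix(0L, g$nrow, g$ncol)
  for (r in regions) cover[region_cell_index(r)] <- cover[region_cell_index(r)] + 1L
  expect_true(all(cover == 1L))     # partition: disjoint and exhaustive
  classes <- vapply(regions, `[[`, "", "nfdc_class")
  expect_equal(sum(classes == "fire-dependent"), 3L)
  expect_equal(sum(classes == "fire-independent"), 1L)
  expect_equal(sum(classes == "fire-sensitive"), 2L)
  expect_error(gen_regions(list(nrow = 1, ncol = 1, xll = 0, yll = 0,
                                cellsize = 1), 6), "capacity")
})

test_that("region masks round-trip through GeoJSON", {
  g <- toy_grid()
  regions <- gen_regions(g, 4)
  path <- tempfile(fileext = ".geojson")
  write_regions_geojson(regions, path)
  back <- read_regions_geojson(path)
  expect_equal(length(back), 4L)
  for (i in seq_along(regions)) {
    expect_identical(back[[i]]$name, regions[[i]]$name)
    expect_identical(back[[i]]$nfdc_class, regions[[i]]$nfdc_class)
    expect_equal(back[[i]]$row_range, regions[[i]]$row_range)
    expect_equal(back[[i]]$col_range, regions[[i]]$col_range)
  }
})

test_that("flat suitability samples points uniformly", {
  cfg <- sim_config(seed = 2)
  clim <- gen_climate_stack(cfg)
  flat <- c(intercept = 0, bio1 = 0, bio9 = 0, bio12 = 0, bio17 = 0)
  fp <- gen_fire_points(clim$present, flat, 10000, seed = 3)
  p <- active_points(fp$occurrences)
  expect_identical(nrow(p), 10000L)
  gx <- cut(p$lon, breaks = seq(-53, -47, length.out = 5))
  gy <- cut(p$lat, breaks = seq(-22, -16, length.out = 5))
  expect_gt(chisq.test(as.vector(table(gx, gy)))$p.value, 0.01)
})

test_that("positive slopes bias sampling toward high values", {
  cfg <- sim_config(seed = 4)
  clim <- gen_climate_stack(cfg)
  co <- c(intercept = 0, bio1 = 3, bio9 = 0, bio12 = 0, bio17 = 0)
  fp <- gen_fire_points(clim$present, co, 3000, seed = 5)
  p <- active_points(fp$occurrences)
  sampled_bio1 <- extract_layer(clim$present$bio1, p$lon, p$lat)
  expect_gt(mean(sampled_bio1, na.rm = TRUE),
            mean(clim$present$bio1$values))
  expect_identical(
    active_points(gen_fire_points(clim$present, co, 500, seed = 9)$occurrences),
    active_points(gen_fire_points(clim$present, co, 500, seed = 9)$occurrences)
  )
})

test_that("a degenerate (constant) stack warns and samples uniformly", {
  st <- const_stack()
  co <- c(intercept = 0, bio1 = 2, bio9 = 0, bio12 = 0, bio17 = 0)
  expect_warning(fp <- gen_fire_points(st, co, 200, seed = 1), "constant")
  expect_identical(nrow(active_points(fp$occurrences)), 200L)
})

test_that("GLM round trip recovers the generating coefficients", {
  # moderate (non-saturating) surface: the log-density contrast of
  # density-proportional sampling matches the logistic score only away
  # from saturation
  co <- c(intercept = -2.5, bio1 = 1.5, bio9 = 0.6, bio12 = -1.0,
          bio17 = -0.5)
  cfg <- sim_config(seed = 1, grid_shape = c(100L, 100L),
                    suitability_coefficients = co)
  clim <- gen_climate_stack(cfg)
  fp <- gen_fire_points(clim$present, co, 5000, seed = 11)
  pa <- sample_pseudoabsences(clim$present, "prevalence", fp$occurrences,
                              seed = 12)
  m <- fit_fire_model("glm", fp$occurrences, pa, clim$present)
  est <- coef(m$fit)[-1]
  std <- est * fp$standardisation$sd[names(est)]
  truth <- co[names(std)]
  expect_true(all(sign(std) == sign(truth)))
  expect_true(all(abs(std / truth - 1) < 0.25))
})

test_that("occurrence tables round-trip through CSV", {
  pts <- data.frame(lon = c(-50.1, -49.2), lat = c(-20.5, -19.9),
                    date = as.Date(c("2015-06-01", "2018-09-30")))
  occ <- occurrence_set(pts)
  path <- tempfile(fileext = ".csv")
  write_occurrences(occ, path)
  back <- read_occurrences(path)
  expect_equal(back$points$lon, pts$lon)
  expect_equal(back$points$lat, pts$lat)
  expect_equal(as.Date(back$points$date), pts$date)
})

test_that("climate layers round-trip through ESRI ASCII grids", {
  set.seed(8)
  v <- matrix(rnorm(48), 6, 8)
  v[2, 3] <- NA
  lay <- climate_layer(v, xll = -53, yll = -22, cellsize = 0.25, name = "bio1")
  path <- tempfile(fileext = ".asc")
  write_ascii_grid(lay, path)
  back <- read_ascii_grid(path, name = "bio1")
  expect_equal(back$values, lay$values, tolerance = 1e-8)
  expect_equal(back$cellsize, 0.25)
  expect_true(is.na(back$values[2, 3]))
})
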