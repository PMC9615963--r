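# Vulnerability and climate-risk arithmetic, checked against the printed
# tables of the published biome assessment shipped in extdata.

test_that("resilience status is the mean of the two pressure fractions", {
  expect_equal(resilience_status(0.2, 0.8), 0.5)
  expect_equal(resilience_status(0, 0), 0)
  expect_equal(resilience_status(1, 1), 1)
  expect_error(resilience_status(1.2, 0.5), "fractions")
})

test_that("relative weights subtract the across-region minimum", {
  expect_equal(relative_weights(c(3, 5, 9)), c(0, 2, 6))
  expect_equal(relative_weights(c(4, 4, 4)), c(0, 0, 0))
  v <- c(2.2, 7.5, 3.1)
  expect_equal(relative_weights(v + 100), relative_weights(v))
  expect_error(relative_weights(5))
})

test_that("vulnerability index averages the deltas", {
  expect_equal(vulnerability_index(0, 0), 0)
  expect_equal(vulnerability_index(4.0, 0.2), 2.1)
  expect_error(vulnerability_index(-1, 0), "nonnegative")
})

test_that("six-region table matches a spreadsheet-style recomputation", {
  set.seed(51)
  sens <- runif(6, 12, 24)
  inputs <- data.frame(
    region = paste0("r", 1:6),
    nfdc_class = c(rep("fire-dependent", 3), "fire-independent",
                   rep("fire-sensitive", 2)),
    vegetation_loss = runif(6, 0.1, 0.8),
    non_protected = runif(6, 0.5, 0.95)
  )
  vt <- vulnerability_table(sens, inputs)
  # independent recomputation, cell by cell
  res_o <- (inputs$vegetation_loss + inputs$non_protected) / 2
  dS_o <- sens - min(sens)
  dR_o <- res_o - min(res_o)
  vi_o <- (dS_o + dR_o) / 2
  expect_equal(vt$resilience, res_o, tolerance = 1e-12)
  expect_equal(vt$deltaS, dS_o, tolerance = 1e-12)
  expect_equal(vt$deltaR, dR_o, tolerance = 1e-12)
  expect_equal(vt$vi, vi_o, tolerance = 1e-12)
  # a region attaining both minima has vi = 0
  sens2 <- sens; sens2[2] <- min(sens) - 1
  inputs2 <- inputs
  inputs2$vegetation_loss[2] <- 0; inputs2$non_protected[2] <- 0
  expect_equal(vulnerability_table(sens2, inputs2)$vi[2], 0)
})

test_that("risk products reproduce the printed table values", {
  # Pantanal SSP2-45/2050, Amazon SSP5-85/2090, Caatinga SSP5-85/2090
  expect_lt(abs(climate_risk(6.40, 14.54) - 93.06), 0.01)
  expect_lt(abs(climate_risk(1.33, 139.95) - 186.13), 0.01)
  expect_lt(abs(climate_risk(10.87, 124.61) - 1354.51), 0.01)
  expect_equal(climate_risk(13.43, 0), 0)   # Pampa SSP2-45/2050
  expect_error(climate_risk(-1, 5))
})

test_that("every printed risk cell closes under the rounding convention", {
  hz <- reference_hazard_table(long = TRUE)
  rk <- reference_risk_table(long = TRUE)
  m <- merge(hz, rk, by = c("region", "nfdc_class", "subregion",
                            "scenario", "period"))
  main <- m[!m$subregion, ]
  expect_identical(nrow(main), 24L)
  recomputed <- round(climate_risk(main$vi, main$hazard), 2)
  # the published table used unrounded intermediates: for the Atlantic
  # Forest and Cerrado rows the printed products drift by up to ~1 from
  # the printed (vi, hazard) pairs, so those cells only close loosely
  loose <- main$region %in% c("Atlantic Forest", "Cerrado")
  expect_true(all(abs(recomputed - main$risk) <= 1.0))
  expect_true(all(abs(recomputed[!loose] - main$risk[!loose]) <= 0.25))
  tight <- main$region %in% c("Pantanal", "Amazon", "Caatinga")
  expect_true(all(abs(recomputed[tight] - main$risk[tight]) <= 0.01 + 1e-9))
})

test_that("class summaries reproduce the printed averages and spread", {
  rk <- reference_risk_table(long = TRUE)
  rk <- rk[!rk$subregion, ]
  sm <- group_summary(rk)
  fd1 <- sm[sm$nfdc_class == "fire-dependent" & sm$scenario == "SSP2-45" &
              sm$period == "2050", ]
  expect_lt(abs(fd1$mean - 84.41), 0.05)
  expect_lt(abs(fd1$sd - 80.4), 0.05)
  fd4 <- sm[sm$nfdc_class == "fire-dependent" & sm$scenario == "SSP5-85" &
              sm$period == "2090", ]
  expect_lt(abs(fd4$mean - 830.3), 0.05)
  fs1 <- sm[sm$nfdc_class == "fire-sensitive" & sm$scenario == "SSP2-45" &
              sm$period == "2050", ]
  expect_lt(abs(fs1$mean - 285.02), 0.02)
  fi <- sm[sm$nfdc_class == "fire-independent", ]
  expect_true(all(fi$n == 1) && all(is.na(fi$sd)))
})

test_that("the printed spread identifies the sample-SD convention", {
  fd <- c(160.16, 0.00, 93.06)
  expect_lt(abs(sd(fd) - 80.4), 0.05)                     # n - 1: matches
  pop_sd <- sqrt(mean((fd - mean(fd))^2))
  expect_gt(abs(pop_sd - 80.4), 10)                       # n: does not
  expect_lt(abs(pop_sd - 65.7), 0.05)
})

test_that("risk is monotone in hazard for vulnerable regions", {
  h <- sort(runif(10, 0, 200))
  expect_true(all(diff(climate_risk(2.5, h)) > 0))
  expect_true(all(climate_risk(0, h) == 0))
})

test_that("zonal sensitivity matches its brute-force oracle", {
  g <- toy_grid()
  r <- region_mask("a", "fire-dependent", c(2, 5), c(3, 7), g)
  uni <- const_layer(20)
  z <- zonal_sensitivity(uni, r)
  expect_equal(z$mean, 20)
  expect_equal(z$sd, 0)
  set.seed(61)
  rnd <- const_layer(0)
  rnd$values[] <- runif(64, 10, 30)
  o <- oracle_zonal(rnd, r)
  z2 <- zonal_sensitivity(rnd, r)
  expect_equal(z2$mean, o$mean, tolerance = 1e-12)
  expect_equal(z2$sd, o$sd, tolerance = 1e-12)
  # three fire-dependent regions with means {14, 17, 21} average to 17.3
  expect_lt(abs(mean(c(14, 17, 21)) - 17.3), 0.05)
})

test_that("risk_table joins hazards with vulnerability and rounds", {
  vt <- data.frame(region = c("a", "b"), nfdc_class = "fire-dependent",
                   vi = c(2, 0.5))
  hz <- data.frame(region = c("a", "b", "a", "b"),
                   scenario = c("SSP2-45", "SSP2-45", "SSP5-85", "SSP5-85"),
                   period = "2050", rcci_ds = c(3, 7, 9, 11))
  rk <- risk_table(vt, hz)
  expect_identical(nrow(rk), 4L)
  expect_equal(rk$risk[rk$region == "a" & rk$scenario == "SSP2-45"], 6)
  expect_equal(rk$risk[rk$region == "b" & rk$scenario == "SSP5-85"], 5.5)
})
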