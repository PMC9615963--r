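# Suitability models, evaluation metrics, selection gates, consensus and
# zonal summaries.

demo_fit_inputs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 1)
      clim <- gen_climate_stack(cfg)
      fp <- gen_fire_points(clim$present, cfg$suitability_coefficients,
                            1500, seed = 2)
      pa <- sample_pseudoabsences(clim$present, "prevalence",
                                  fp$occurrences, seed = 3)
      cache <<- list(clim = clim, fp = fp, pa = pa)
    }
    cache
  }
})

test_that("envelope scores peak at the presence median and vanish outside", {
  d <- demo_fit_inputs()
  m <- fit_fire_model("envelope", d$fp$occurrences, d$pa, d$clim$present)
  pv <- m$fit$presence_values
  center <- as.data.frame(lapply(pv, median))
  expect_gt(predict(m, center), 0.9)
  outside <- as.data.frame(lapply(pv, function(v) max(v) + 1))
  expect_equal(unname(predict(m, outside)), 0)
  # beyond the envelope on a single variable is enough to zero the score
  one_out <- center
  one_out$bio1 <- min(pv$bio1) - 1
  expect_equal(unname(predict(m, one_out)), 0)
})

test_that("glm fit separates presences from background", {
  d <- demo_fit_inputs()
  m <- fit_fire_model("glm", d$fp$occurrences, d$pa, d$clim$present)
  met <- evaluate_model(m, d$fp$occurrences, d$pa, d$clim$present)
  expect_gt(met$auc, 0.8)
  # with strongly collinear temperature layers the identifiable quantities
  # are the grouped loadings: warm means more fire, wet means less
  est <- coef(m$fit)[-1]
  sds <- vapply(d$clim$present, function(l) sd(l$values), numeric(1))
  std <- est * sds[names(est)]
  expect_gt(std[["bio1"]] + std[["bio9"]], 0)
  expect_lt(std[["bio12"]] + std[["bio17"]], 0)
})

test_that("svm probabilities are bounded and discriminate", {
  d <- demo_fit_inputs()
  m <- fit_fire_model("svm", d$fp$occurrences, d$pa, d$clim$present, seed = 4)
  pred <- predict(m, d$clim$present)
  expect_true(all(pred$values >= 0 & pred$values <= 1))
  met <- evaluate_model(m, d$fp$occurrences, d$pa, d$clim$present)
  expect_gt(met$auc, 0.7)
})

test_that("too few presences and collinear variables are handled", {
  d <- demo_fit_inputs()
  few <- occurrence_set(active_points(d$fp$occurrences)[1:5, ])
  expect_error(fit_fire_model("glm", few, d$pa, d$clim$present),
               "at least 20")
  # make bio9 an exact affine copy of bio1
  st <- d$clim$present
  st$bio9$values <- 2 * st$bio1$values + 1
  expect_warning(
    m <- fit_fire_model("glm", d$fp$occurrences, d$pa, st),
    "collinear"
  )
  expect_false("bio9" %in% m$variables)
})

test_that("evaluation metrics follow the rank and threshold definitions", {
  m <- evaluate_model(c(0.9, 0.8), absence_scores = c(0.2, 0.1))
  expect_equal(m$auc, 1)
  expect_equal(m$tss, 1)
  expect_equal(m$threshold, 0.8)  # highest threshold among the maximisers

  same <- evaluate_model(rep(0.4, 5), absence_scores = rep(0.4, 5))
  expect_equal(same$auc, 0.5)
  expect_equal(same$tss, 0)
  expect_true(same$degenerate)

  set.seed(31)
  rnd <- evaluate_model(runif(1000), absence_scores = runif(1000))
  expect_lt(abs(rnd$auc - 0.5), 0.05)
})

test_that("rank-statistic AUC agrees with an independent ROC library", {
  skip_if_not_installed("pROC")
  set.seed(13)
  ps <- rbeta(300, 4, 2)
  as <- rbeta(300, 2, 4)
  ours <- evaluate_model(ps, absence_scores = as)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = c(rep(1, 300), rep(0, 300)), predictor = c(ps, as),
    quiet = TRUE
  )))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("selection applies all three gates and reports failures", {
  metrics <- data.frame(
    auc = c(0.75, 0.69, 0.75, 0.90),
    tss = c(0.40, 0.40, 0.40, 0.20),
    threshold = c(0.85, 0.85, 0.79, 0.85)
  )
  expect_identical(select_models(metrics), 1L)
  expect_error(select_models(metrics[2:3, ]),
               "1 failed AUC.*1 failed threshold")
})

test_that("consensus is the weight-normalised mix of member maps", {
  d <- demo_fit_inputs()
  m1 <- fit_fire_model("glm", d$fp$occurrences, d$pa, d$clim$present)
  met1 <- evaluate_model(m1, d$fp$occurrences, d$pa, d$clim$present)
  single <- consensus_map(list(m1), list(met1), d$clim$present)
  expect_equal(single$layer$values, predict(m1, d$clim$present)$values)
  expect_equal(single$weights, 1)

  # two stub members valued 0 and 1 everywhere, accuracy weights 3:1
  .S3method("predict", "const_sdm", function(object, newdata, ...) {
    out <- newdata[[1]]
    out$values[] <- object$value
    out
  })
  stub <- function(v, alg) structure(list(value = v, algorithm = alg),
                                     class = "const_sdm")
  mets <- data.frame(tss = c(0.75, 0.25), auc = c(0.9, 0.9))
  cm <- consensus_map(list(stub(0, "a"), stub(1, "b")), mets, d$clim$present)
  expect_true(all(cm$layer$values == 0.25))
  expect_equal(cm$weights, c(0.75, 0.25))

  # cellwise bounds: min member <= consensus <= max member
  m2 <- fit_fire_model("envelope", d$fp$occurrences, d$pa, d$clim$present)
  met2 <- evaluate_model(m2, d$fp$occurrences, d$pa, d$clim$present)
  cons <- consensus_map(list(m1, m2), list(met1, met2), d$clim$present)
  p1 <- predict(m1, d$clim$present)$values
  p2 <- predict(m2, d$clim$present)$values
  expect_true(all(cons$layer$values >= pmin(p1, p2) - 1e-12))
  expect_true(all(cons$layer$values <= pmax(p1, p2) + 1e-12))
  expect_equal(sum(cons$weights), 1)
})

test_that("zonal suitability matches the brute-force cell loop", {
  g <- toy_grid()
  regions <- gen_regions(g, 4)
  uni <- const_layer(0.5)
  z <- zonal_suitability(uni, regions)
  expect_true(all(z$mean == 0.5) && all(z$sd == 0))

  half <- const_layer(0)
  half$values[, 1:4] <- 1
  r_all <- region_mask("all", "fire-dependent", c(1, 8), c(1, 8), g)
  z2 <- zonal_suitability(half, list(r_all))
  expect_equal(z2$mean, 0.5)
  expect_equal(z2$sd, 0.5)

  set.seed(17)
  rnd <- const_layer(0)
  rnd$values[] <- runif(64)
  for (r in regions) {
    o <- oracle_zonal(rnd, r)
    z3 <- zonal_mean_sd(rnd, r)
    expect_equal(z3$mean, o$mean, tolerance = 1e-12)
    expect_equal(z3$sd, o$sd, tolerance = 1e-12)
  }
})

test_that("projection onto the training stack reproduces training scores", {
  d <- demo_fit_inputs()
  m <- fit_fire_model("glm", d$fp$occurrences, d$pa, d$clim$present)
  pts <- active_points(d$fp$occurrences)[1:50, ]
  direct <- predict(m, extract_stack(d$clim$present, pts$lon, pts$lat))
  via_map <- extract_layer(predict(m, d$clim$present), pts$lon, pts$lat)
  # cell-centre evaluation vs point evaluation agree at cell resolution
  expect_gt(cor(direct, via_map), 0.98)
})
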