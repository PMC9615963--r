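# Correlative fire-suitability models: bioclimatic envelope, logistic GLM
# and SVM, with AUC/TSS/threshold evaluation, gate-based selection and an
# accuracy-weighted consensus projection.

#' Fit a climate-fire suitability model
#'
#' Fits one of three presence/pseudoabsence algorithms on the bioclim
#' values extracted at the point locations:
#' \describe{
#'   \item{envelope}{classic bioclimatic envelope: each variable scored by
#'     its two-tailed percentile position among the presence values,
#'     `2 * min(p, 1 - p)` (1 at the presence median, 0 at or beyond the
#'     presence min/max), aggregated across variables by the minimum.}
#'   \item{glm}{logistic regression with linear terms.}
#'   \item{svm}{radial-kernel support vector machine with Platt probability
#'     calibration.}
#' }
#' Points whose extraction hits nodata are dropped; perfectly collinear
#' variables are dropped with a warning.
#'
#' @param algorithm `"envelope"`, `"glm"` or `"svm"`.
#' @param presences,absences [occurrence_set()]s (active points are used).
#' @param stack A [climate_stack()] supplying the predictor layers.
#' @param seed Integer seed (the SVM probability calibration is stochastic).
#' @return An object of class `fire_sdm` with a [predict.fire_sdm()] method.
#' @export
fit_fire_model <- function(algorithm = c("envelope", "glm", "svm"),
                           presences, absences, stack, seed = 1L) {
  algorithm <- match.arg(algorithm)
  pd <- stats::na.omit(extract_points(stack, presences))
  ad <- stats::na.omit(extract_points(stack, absences))
  if (nrow(pd) < 20L) stop("need at least 20 presences with climate values",
                           call. = FALSE)
  vars <- names(stack)
  # drop perfectly collinear predictors (keep the first of each pair)
  if (length(vars) > 1L) {
    cm <- suppressWarnings(stats::cor(pd[vars]))
    cm[!is.finite(cm)] <- 0
    drop <- character(0)
    for (i in seq_along(vars)[-1L]) {
      if (any(abs(cm[i, seq_len(i - 1L)]) > 0.9999)) drop <- c(drop, vars[i])
    }
    if (length(drop)) {
      warning("dropping collinear variable(s): ", paste(drop, collapse = ", "),
              call. = FALSE)
      vars <- setdiff(vars, drop)
    }
  }
  fit <- switch(
    algorithm,
    envelope = list(presence_values = pd[vars]),
    glm = {
      df <- rbind(cbind(pd[vars], y = 1), cbind(ad[vars], y = 0))
      stats::glm(y ~ ., family = stats::binomial(), data = df)
    },
    svm = {
      x <- rbind(pd[vars], ad[vars])
      y <- factor(c(rep(1L, nrow(pd)), rep(0L, nrow(ad))), levels = c(0L, 1L))
      with_seed(seed, e1071::svm(x, y, probability = TRUE, kernel = "radial"))
    }
  )
  structure(list(algorithm = algorithm, variables = vars, fit = fit,
                 n_presence = nrow(pd), n_absence = nrow(ad)),
            class = "fire_sdm")
}

extract_points <- function(stack, occ) {
  pts <- if (inherits(occ, "occurrence_set")) active_points(occ) else occ
  extract_stack(stack, pts$lon, pts$lat)
}

#' @export
print.fire_sdm <- function(x, ...) {
  cat(sprintf("<fire_sdm %s> %d presences / %d absences, variables: %s\n",
              x$algorithm, x$n_presence, x$n_absence,
              paste(x$variables, collapse = ", ")))
  invisible(x)
}

#' Predict fire-occurrence probability
#'
#' @param object A `fire_sdm`.
#' @param newdata A [climate_stack()] (returns a probability
#'   [climate_layer()]) or a data frame of predictor columns (returns a
#'   numeric vector in [0, 1]).
#' @param ... Unused.
#' @export
predict.fire_sdm <- function(object, newdata, ...) {
  if (inherits(newdata, "climate_stack")) {
    ref <- newdata[[1L]]
    df <- as.data.frame(lapply(newdata[object$variables], function(l) {
      as.vector(l$values)
    }))
    p <- predict_scores(object, df)
    out <- ref
    out$values <- matrix(p, nrow(ref$values), ncol(ref$values))
    out$name <- paste0("suitability_", object$algorithm)
    return(out)
  }
  predict_scores(object, as.data.frame(newdata)[object$variables])
}

predict_scores <- function(object, df) {
  ok <- stats::complete.cases(df)
  p <- rep(NA_real_, nrow(df))
  if (!any(ok)) return(p)
  d <- df[ok, , drop = FALSE]
  p[ok] <- switch(
    object$algorithm,
    envelope = {
      pv <- object$fit$presence_values
      scores <- sapply(object$variables, function(v) {
        ref <- sort(pv[[v]])
        pos <- (findInterval(d[[v]], ref, rightmost.closed = FALSE)) /
          length(ref)
        s <- 2 * pmin(pos, 1 - pos)
        s[d[[v]] < ref[1L] | d[[v]] > ref[length(ref)]] <- 0
        s
      })
      if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1L)
      apply(scores, 1L, min)
    },
    glm = stats::predict(object$fit, newdata = d, type = "response"),
    svm = {
      pr <- stats::predict(object$fit, d, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    }
  )
  pmin(pmax(p, 0), 1)
}

#' Evaluate presence/absence discrimination
#'
#' Computes the rank-statistic AUC, the score threshold maximising
#' sensitivity + specificity (ties resolved to the highest threshold;
#' points scoring at or above the threshold are classified presence), and
#' the TSS (sensitivity + specificity - 1) at that threshold.
#'
#' Accepts either a fitted model with test [occurrence_set()]s and a stack,
#' or two bare score vectors.
#'
#' @param model A `fire_sdm`, or a numeric vector of presence scores.
#' @param test_presences,test_absences [occurrence_set()]s, or (when
#'   `model` is numeric via `absence_scores`) ignored.
#' @param stack [climate_stack()] for extraction (model form only).
#' @param absence_scores Numeric absence scores (score-vector form).
#' @return List of class `sdm_metrics`: `auc`, `tss`, `threshold`,
#'   `sensitivity`, `specificity`, `degenerate`.
#' @export
evaluate_model <- function(model, test_presences = NULL, test_absences = NULL,
                           stack = NULL, absence_scores = NULL) {
  if (inherits(model, "fire_sdm")) {
    ps <- predict_scores(model, stats::na.omit(extract_points(stack, test_presences)))
    as <- predict_scores(model, stats::na.omit(extract_points(stack, test_absences)))
  } else {
    ps <- as.numeric(model)
    as <- as.numeric(absence_scores %||% test_absences)
  }
  ps <- ps[is.finite(ps)]; as <- as[is.finite(as)]
  if (length(ps) == 0L || length(as) == 0L) {
    stop("both test sets must yield scores", call. = FALSE)
  }
  # rank-statistic AUC (Mann-Whitney with ties at 1/2)
  r <- rank(c(ps, as))
  auc <- (sum(r[seq_along(ps)]) - length(ps) * (length(ps) + 1) / 2) /
    (length(ps) * length(as))
  cand <- sort(unique(c(ps, as)), decreasing = TRUE)
  sens <- vapply(cand, function(t) mean(ps >= t), numeric(1))
  spec <- vapply(cand, function(t) mean(as < t), numeric(1))
  best <- which.max(sens + spec)   # cand is decreasing: first max = highest
  degenerate <- length(cand) == 1L
  structure(
    list(auc = auc, tss = sens[best] + spec[best] - 1, threshold = cand[best],
         sensitivity = sens[best], specificity = spec[best],
         degenerate = degenerate),
    class = "sdm_metrics"
  )
}

#' @export
print.sdm_metrics <- function(x, ...) {
  cat(sprintf("AUC %.3f | TSS %.3f | threshold %.3f%s\n",
              x$auc, x$tss, x$threshold,
              if (x$degenerate) " (degenerate scores)" else ""))
  invisible(x)
}

#' Select models passing the accuracy gates
#'
#' Keeps a candidate iff AUC > `auc_min`, TSS > `tss_min` and the
#' max-sens+spec threshold > `threshold_min` (defaults: 0.7, 0.3, 0.8).
#'
#' @param metrics Data frame with columns `auc`, `tss`, `threshold` (one
#'   row per candidate), or a list of `sdm_metrics`.
#' @param auc_min,tss_min,threshold_min Gate values.
#' @return Integer indices of the kept candidates.
#' @export
select_models <- function(metrics, auc_min = 0.7, tss_min = 0.3,
                          threshold_min = 0.8) {
  if (!is.data.frame(metrics)) {
    metrics <- do.call(rbind, lapply(metrics, function(m) {
      data.frame(auc = m$auc, tss = m$tss, threshold = m$threshold)
    }))
  }
  stopifnot(nrow(metrics) >= 1L)
  keep <- metrics$auc > auc_min & metrics$tss > tss_min &
    metrics$threshold > threshold_min
  if (!any(keep)) {
    stop(sprintf(
      paste0("no model passed selection: %d failed AUC > %g, ",
             "%d failed TSS > %g, %d failed threshold > %g"),
      sum(metrics$auc <= auc_min), auc_min,
      sum(metrics$tss <= tss_min), tss_min,
      sum(metrics$threshold <= threshold_min), threshold_min
    ), call. = FALSE)
  }
  which(keep)
}

#' Accuracy-weighted consensus projection
#'
#' Cellwise weighted mean of the member probability maps, weights
#' proportional to each member's accuracy metric (TSS by default,
#' configurable to AUC), normalised to sum to 1.
#'
#' @param models List of `fire_sdm` objects (the kept members).
#' @param metrics Parallel list/data frame of their evaluation metrics.
#' @param stack [climate_stack()] to project onto.
#' @param weight_by `"tss"` or `"auc"`.
#' @return List of class `consensus_map`: `layer` (a [climate_layer()]),
#'   `weights`, `member_algorithms`.
#' @export
consensus_map <- function(models, metrics, stack, weight_by = c("tss", "auc")) {
  weight_by <- match.arg(weight_by)
  stopifnot(length(models) >= 1L)
  w <- if (is.data.frame(metrics)) metrics[[weight_by]] else {
    vapply(metrics, `[[`, numeric(1), weight_by)
  }
  w <- pmax(w, 0)
  if (sum(w) == 0) {
    warning("all-zero weights; falling back to equal weights", call. = FALSE)
    w <- rep(1, length(models))
  }
  w <- w / sum(w)
  preds <- lapply(models, stats::predict, newdata = stack)
  acc <- Reduce(`+`, Map(function(p, wi) p$values * wi, preds, w))
  out <- preds[[1L]]
  out$values <- acc
  out$name <- "suitability_consensus"
  structure(
    list(layer = out, weights = w,
         member_algorithms = vapply(models, `[[`, "", "algorithm")),
    class = "consensus_map"
  )
}

#' @export
print.consensus_map <- function(x, ...) {
  cat(sprintf("<consensus_map> %d member(s): %s (weights %s)\n",
              length(x$weights),
              paste(x$member_algorithms, collapse = ", "),
              paste(sprintf("%.2f", x$weights), collapse = ", ")))
  invisible(x)
}

#' Per-region suitability summary
#'
#' Mean and population SD of the consensus probability inside each region
#' mask, nodata excluded (reported as proportions in [0, 1]).
#'
#' @param map A `consensus_map` or [climate_layer()].
#' @param regions List of [region_mask()]s.
#' @return Data frame `region`, `nfdc_class`, `mean`, `sd`, `n_cells`.
#' @export
zonal_suitability <- function(map, regions) {
  layer <- if (inherits(map, "consensus_map")) map$layer else map
  do.call(rbind, lapply(regions, function(r) {
    z <- zonal_mean_sd(layer, r)
    data.frame(region = r$name, nfdc_class = r$nfdc_class,
               mean = z$mean, sd = z$sd, n_cells = z$n_cells)
  }))
}

#' Run the full suitability protocol
#'
#' Replicated 70/30 evaluation of the three algorithms, gate-based
#' selection, accuracy-weighted consensus and projection to the present
#' and any future stacks. Splits are stratified by class and re-drawn per
#' replicate with seed `seed + replicate`; the SVM is fitted in
#' occurrence-prevalence mode (as many pseudoabsences as presences), the
#' envelope and GLM on the full pseudoabsence set.
#'
#' @param presences [occurrence_set()] of modelling presences.
#' @param absences [occurrence_set()] of pseudoabsences.
#' @param stack Present-day [climate_stack()].
#' @param future Optional nested list `scenario -> period -> climate_stack`.
#' @param n_replicates Replicates per algorithm (default 10).
#' @param algorithms Algorithms to run.
#' @param seed Root seed.
#' @param auc_min,tss_min,threshold_min Selection gates (defaults 0.7 /
#'   0.3 / 0.8).
#' @param weight_by Consensus weighting metric.
#' @return Object of class `suitability_run`: `metrics` (one row per
#'   algorithm x replicate with `kept`), `consensus` (present), `future`
#'   (nested consensus maps), `models` (kept fits).
#' @export
run_suitability <- function(presences, absences, stack, future = NULL,
                            n_replicates = 10L,
                            algorithms = c("envelope", "glm", "svm"),
                            seed = 1L, auc_min = 0.7, tss_min = 0.3,
                            threshold_min = 0.8,
                            weight_by = "tss") {
  pres <- active_points(presences)
  abs_ <- active_points(absences)
  models <- list()
  rows <- list()
  k <- 0L
  for (rep_i in seq_len(n_replicates)) {
    sp <- with_seed(split_seed(seed, rep_i), {
      list(p = sample(c(TRUE, FALSE), nrow(pres), replace = TRUE, prob = c(0.7, 0.3)),
           a = sample(c(TRUE, FALSE), nrow(abs_), replace = TRUE, prob = c(0.7, 0.3)))
    })
    p_train <- occurrence_set(pres[sp$p, , drop = FALSE])
    p_test <- occurrence_set(pres[!sp$p, , drop = FALSE])
    a_train <- occurrence_set(abs_[sp$a, , drop = FALSE])
    a_test <- occurrence_set(abs_[!sp$a, , drop = FALSE])
    # prevalence-mode pseudoabsence subset for the SVM
    a_prev_idx <- with_seed(split_seed(seed, 1000L + rep_i), {
      sample(which(sp$a), min(sum(sp$p), sum(sp$a)))
    })
    a_prev <- occurrence_set(abs_[a_prev_idx, , drop = FALSE])
    for (alg in algorithms) {
      k <- k + 1L
      fit <- fit_fire_model(
        alg, p_train, if (alg == "svm") a_prev else a_train, stack,
        seed = split_seed(seed, 2000L + k)
      )
      m <- evaluate_model(fit, p_test, a_test, stack)
      models[[k]] <- fit
      rows[[k]] <- data.frame(algorithm = alg, replicate = rep_i,
                              auc = m$auc, tss = m$tss,
                              threshold = m$threshold)
    }
  }
  metrics <- do.call(rbind, rows)
  kept <- select_models(metrics, auc_min, tss_min, threshold_min)
  metrics$kept <- seq_len(nrow(metrics)) %in% kept
  cons <- consensus_map(models[kept], metrics[kept, ], stack,
                        weight_by = weight_by)
  fut <- NULL
  if (!is.null(future)) {
    fut <- lapply(future, function(periods) {
      lapply(periods, function(fs) {
        consensus_map(models[kept], metrics[kept, ], fs, weight_by = weight_by)
      })
    })
  }
  structure(
    list(metrics = metrics, consensus = cons, future = fut,
         models = models[kept]),
    class = "suitability_run"
  )
}

#' @export
print.suitability_run <- function(x, ...) {
  cat(sprintf("<suitability_run> %d models evaluated, %d kept (%s)\n",
              nrow(x$metrics), sum(x$metrics$kept),
              paste(unique(x$metrics$algorithm[x$metrics$kept]),
                    collapse = ", ")))
  print(stats::aggregate(cbind(auc, tss, threshold) ~ algorithm,
                         data = x$metrics, FUN = mean))
  invisible(x)
}
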