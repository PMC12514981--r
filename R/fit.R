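#' Fit a cycloplegic-refraction prediction model
#'
#' The central fitting routine: assembles the requested group's feature
#' table from raw per-eye records ([build_features()]), splits off a test
#' set, imputes missing cells with training-row medians, screens features by
#' cross-validated lasso ([lasso_screen()]), tunes and fits a
#' gradient-boosted regressor ([train_gbt()]), and evaluates it on the held
#' out eyes with the full battery: error metrics, paired t-test,
#' Bland-Altman limits of agreement, age-subgroup metrics and linear/SVM
#' baselines. Imputation, screening and tuning only ever see training rows.
#'
#' @param records raw per-eye records (see [build_features()]) including the
#'   training target `cyclo_S`.
#' @param group model group: `"control"`, `"IOLe"`, `"IOLm"` or `"IOLcl"`.
#' @param config an [experiment_config()].
#' @param split optional precomputed split (list with `train_idx`,
#'   `test_idx`) so several groups share one split; computed from
#'   `config` otherwise.
#' @param constants an [optical_constants()] object for the lens features.
#' @return an object of class `cyclo_fit` with `print()`, `summary()`,
#'   `coef()`, `predict()`, `residuals()` and `plot()` methods.
#' @examples
#' \donttest{
#' rec <- generate_cohort(cohort_config(n_eyes = 80), seed = 7)
#' cfg <- experiment_config(gbt_grid = expand.grid(eta = 0.1, max_depth = 3,
#'                                                 subsample = 1, lambda = 1),
#'                          nrounds = 50, seed = 7)
#' fit <- fit_cyclo(rec, "IOLcl", cfg)
#' summary(fit)
#' }
#' @export
fit_cyclo <- function(records, group = "IOLcl", config = experiment_config(),
                      split = NULL, constants = optical_constants()) {
  if (!"cyclo_S" %in% names(records))
    stop("records must contain the training target 'cyclo_S'")
  ft <- build_features(records, group, k = constants)
  if (is.null(split))
    split <- split_train_test(ft, config$test_fraction,
                              grouped = config$subject_grouped_split,
                              seed = config$seed)
  imputed <- impute_missing(ft, split$train_idx)
  medians <- attr(imputed, "medians")
  train <- imputed[split$train_idx, , drop = FALSE]
  test <- imputed[split$test_idx, , drop = FALSE]

  screen <- lasso_screen(train, lambda = config$lasso_lambda_grid,
                         folds = config$cv_folds, seed = config$seed)
  gbt <- train_gbt(train, screen$selected, config$gbt_grid,
                   folds = config$cv_folds, nrounds = config$nrounds,
                   seed = config$seed)
  pred <- stats::predict(gbt$booster,
                         as.matrix(test[, gbt$selected, drop = FALSE]))
  truth <- test$cyclo_S
  obj <- list(group = group, config = config, constants = constants,
              split = split, medians = medians, screen = screen, gbt = gbt,
              train = train, test = test, pred = pred,
              metrics = evaluate_predictions(pred, truth),
              ttest = paired_ttest(pred, truth),
              loa = limits_of_agreement(pred, truth),
              subgroups = subgroup_eval(pred, truth, test$age,
                                        config$age_bins),
              baselines = baseline_models(train, test, screen$selected,
                                          folds = config$cv_folds,
                                          seed = config$seed))
  class(obj) <- "cyclo_fit"
  obj
}

#' Predict cycloplegic sphere for new eyes
#'
#' @param object a [fit_cyclo()] model.
#' @param newdata raw per-eye records (feature derivation is applied) or an
#'   already-built feature table for the model's group. Missing cells are
#'   filled with the training medians.
#' @param ... unused.
#' @return numeric vector of predicted cycloplegic sphere, D.
#' @export
predict.cyclo_fit <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$pred)
  if (!all(object$gbt$selected %in% names(newdata)))
    newdata <- build_features(newdata, object$group, k = object$constants)
  for (cl in names(object$medians)) {
    if (!cl %in% names(newdata)) next
    miss <- is.na(newdata[[cl]])
    if (any(miss)) newdata[[cl]][miss] <- object$medians[[cl]]
  }
  stats::predict(object$gbt$booster,
                 as.matrix(newdata[, object$gbt$selected, drop = FALSE]))
}

#' @export
coef.cyclo_fit <- function(object, ...) object$screen$coefficients

#' @export
residuals.cyclo_fit <- function(object, type = c("test", "train"), ...) {
  type <- match.arg(type)
  d <- object[[type]]
  pr <- if (type == "test") object$pred else
    stats::predict(object$gbt$booster,
                   as.matrix(d[, object$gbt$selected, drop = FALSE]))
  pr - d$cyclo_S
}

#' @method print cyclo_fit
#' @export
print.cyclo_fit <- function(x, ...) {
  cat(sprintf("Cycloplegic sphere model -- %s group\n", x$group))
  cat(sprintf("  train/test eyes: %d/%d\n", nrow(x$train), nrow(x$test)))
  cat(sprintf("  screened features (%d): %s\n", length(x$gbt$selected),
              paste(x$gbt$selected, collapse = ", ")))
  bp <- x$gbt$best_params
  cat(sprintf("  boosting: eta=%.2f depth=%d subsample=%.1f lambda=%.1f (%d rounds)\n",
              bp$eta, bp$max_depth, bp$subsample, bp$lambda, x$gbt$nrounds))
  m <- x$metrics
  cat(sprintf("  test: MAE=%.3f MSE=%.3f RMSE=%.3f r2=%.3f within 0.50 D=%.1f%%\n",
              m$mae, m$mse, m$rmse, m$r2, m$pct_within_half_D))
  invisible(x)
}

#' @method summary cyclo_fit
#' @export
summary.cyclo_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.cyclo_fit")
}

#' @method print summary.cyclo_fit
#' @export
print.summary.cyclo_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  tt <- f$ttest; lo <- f$loa
  cat(sprintf("  paired t-test: MD=%.3f +/- %.3f, t=%.2f, p=%.3g (n=%d)\n",
              tt$mean_diff, tt$sd, tt$t, tt$p, tt$n))
  cat(sprintf("  95%% LOA: %.3f +/- %.3f  [%.3f, %.3f]\n",
              lo$mean_diff, lo$half_width, lo$lower, lo$upper))
  for (nm in names(f$subgroups)) {
    sg <- f$subgroups[[nm]]
    if (is.null(sg$metrics)) {
      cat(sprintf("  age %s y: empty bin\n", nm))
    } else {
      cat(sprintf("  age %s y (n=%d%s): MAE=%.3f RMSE=%.3f r2=%.3f\n", nm,
                  sg$n, if (sg$flagged) ", flagged" else "",
                  sg$metrics$mae, sg$metrics$rmse, sg$metrics$r2))
    }
  }
  bl <- f$baselines
  cat(sprintf("  baseline linear: RMSE=%.3f r2=%.3f | SVM (cost=%g): RMSE=%.3f r2=%.3f\n",
              bl$linear$metrics$rmse, bl$linear$metrics$r2, bl$svm$cost,
              bl$svm$metrics$rmse, bl$svm$metrics$r2))
  invisible(x)
}

#' Bland-Altman plot of the held-out predictions
#'
#' @param x a [fit_cyclo()] model.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cyclo_fit <- function(x, ...) {
  truth <- x$test$cyclo_S
  d <- x$pred - truth
  m <- (x$pred + truth) / 2
  graphics::plot(m, d, xlab = "Mean of predicted and true cyclo S (D)",
                 ylab = "Predicted - true (D)",
                 main = sprintf("Bland-Altman, %s group", x$group), ...)
  graphics::abline(h = x$loa$mean_diff, lty = 1)
  graphics::abline(h = c(x$loa$lower, x$loa$upper), lty = 2)
  invisible(x)
}
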