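#' Configuration of a prediction experiment
#'
#' @param groups model groups to run; see [feature_columns()].
#' @param test_fraction held-out fraction (default 0.20).
#' @param cv_folds folds for cross-validated screening and tuning.
#' @param lasso_lambda_grid decreasing positive L1 penalty grid.
#' @param gbt_grid data.frame of gradient-boosting hyperparameter cells with
#'   columns `eta` (learning rate), `max_depth`, `subsample`, `lambda` (L2
#'   regularisation). The default spans all four knobs at desk scale.
#' @param nrounds boosting rounds per configuration.
#' @param subject_grouped_split keep both eyes of a subject on the same side
#'   of the split (recommended for inference on new subjects; default FALSE,
#'   matching eye-level evaluation).
#' @param age_bins list of inclusive age intervals (years) for subgroup
#'   evaluation; an eye falls in the first interval `[lo, hi]` containing
#'   `floor(age)`.
#' @param seed master seed controlling split, fold assignment and tuning.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(groups = c("control", "IOLe", "IOLm", "IOLcl"),
                              test_fraction = 0.20, cv_folds = 5,
                              lasso_lambda_grid = 10^seq(0.5, -4, length.out = 60),
                              gbt_grid = expand.grid(
                                eta = c(0.05, 0.1, 0.3),
                                max_depth = c(2, 3, 4),
                                subsample = c(0.7, 1.0),
                                lambda = c(0.1, 1, 10)),
                              nrounds = 100,
                              subject_grouped_split = FALSE,
                              age_bins = list(c(4, 8), c(9, 15)),
                              seed = 1L) {
  groups <- match.arg(groups, several.ok = TRUE)
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must be in (0, 1)")
  if (cv_folds < 2) stop("cv_folds must be >= 2")
  if (!length(lasso_lambda_grid) || any(lasso_lambda_grid <= 0))
    stop("lasso_lambda_grid must be nonempty and positive")
  if (!nrow(gbt_grid)) stop("gbt_grid must be nonempty")
  structure(list(groups = groups, test_fraction = test_fraction,
                 cv_folds = cv_folds, lasso_lambda_grid = sort(lasso_lambda_grid,
                                                               decreasing = TRUE),
                 gbt_grid = gbt_grid, nrounds = nrounds,
                 subject_grouped_split = subject_grouped_split,
                 age_bins = age_bins, seed = as.integer(seed)),
            class = "experiment_config")
}

#' Random train/test split
#'
#' Disjoint, exhaustive split with `round((1 - test_fraction) * n)` training
#' rows. With `grouped = TRUE` both eyes of a subject land on the same side
#' (subjects are accumulated in random order until the training quota is
#' closest).
#'
#' @param table a data.frame; needs a `subject_id` column when `grouped`.
#' @param test_fraction held-out fraction.
#' @param grouped subject-grouped split.
#' @param seed integer seed.
#' @return list with integer row indices `train_idx` and `test_idx`.
#' @export
split_train_test <- function(table, test_fraction = 0.20, grouped = FALSE,
                             seed = 1L) {
  n <- nrow(table)
  if (n < 10) stop("need at least 10 rows to split")
  set.seed(as.integer(seed))
  n_train <- round((1 - test_fraction) * n)
  if (!grouped) {
    train_idx <- sort(sample.int(n, n_train))
  } else {
    subj <- unique(table$subject_id)
    ord <- sample(subj)
    sizes <- cumsum(as.integer(table(factor(table$subject_id,
                                            levels = ord))[ord]))
    k <- which.min(abs(sizes - n_train))
    train_idx <- sort(which(table$subject_id %in% ord[seq_len(k)]))
  }
  list(train_idx = train_idx, test_idx = setdiff(seq_len(n), train_idx))
}

#' Train-median imputation
#'
#' Fills every missing feature cell with the column median computed on the
#' training rows only; the same medians are reused on test rows, so no
#' test-set information leaks into imputation.
#'
#' @param table a feature table (see [build_features()]).
#' @param train_idx rows on which medians are computed (default: all rows).
#' @param feature_cols columns to impute (default: every numeric column
#'   except identifiers and the target).
#' @return the table with all feature cells filled; the medians used are
#'   attached as attribute `"medians"`.
#' @export
impute_missing <- function(table, train_idx = seq_len(nrow(table)),
                           feature_cols = NULL) {
  if (is.null(feature_cols))
    feature_cols <- setdiff(names(table)[vapply(table, is.numeric, TRUE)],
                            c("cyclo_S", "cyclo_C"))
  med <- vapply(feature_cols, function(cl)
    stats::median(table[[cl]][train_idx], na.rm = TRUE), numeric(1))
  if (any(is.na(med)))
    stop("unimputable: column(s) entirely missing on training rows: ",
         paste(feature_cols[is.na(med)], collapse = ", "))
  for (cl in feature_cols) {
    miss <- is.na(table[[cl]])
    if (any(miss)) table[[cl]][miss] <- med[[cl]]
  }
  attr(table, "medians") <- med
  table
}

# deterministic fold assignment
.make_foldid <- function(n, folds, seed) {
  set.seed(as.integer(seed))
  sample(rep_len(seq_len(folds), n))
}

#' L1-penalised feature screening
#'
#' Standardises the training features, runs cross-validated lasso regression
#' over the penalty grid, and returns the features with nonzero coefficients
#' at the CV-mean-squared-error-minimising penalty. If that penalty zeroes
#' everything, the least-penalised lambda with at least one nonzero
#' coefficient is used instead, so the screen never returns an empty set.
#'
#' @param train a feature table including the target column.
#' @param target name of the target column.
#' @param lambda decreasing positive penalty grid.
#' @param folds number of CV folds.
#' @param seed integer seed (fold assignment).
#' @return list with `selected` (feature names), `coefficients` (named
#'   nonzero coefficients at the chosen penalty, original scale), `lambda`
#'   (chosen penalty) and `cv` (data.frame of lambda vs CV error).
#' @export
lasso_screen <- function(train, target = "cyclo_S",
                         lambda = 10^seq(0.5, -4, length.out = 60),
                         folds = 5, seed = 1L) {
  feats <- setdiff(names(train)[vapply(train, is.numeric, TRUE)], target)
  if (length(feats) < 2) stop("need at least two candidate features")
  y <- train[[target]]
  if (is.null(y) || any(is.na(y))) stop("target column must be complete")
  if (stats::var(y) == 0) stop("degenerate: constant target")
  x <- as.matrix(train[, feats])
  foldid <- .make_foldid(nrow(x), folds, seed)
  cv <- glmnet::cv.glmnet(x, y, alpha = 1, lambda = sort(lambda, decreasing = TRUE),
                          standardize = TRUE, foldid = foldid)
  pick <- cv$lambda.min
  nz_tol <- 1e-10  # glmnet can leave machine-noise coefficients on duplicates
  cf <- stats::coef(cv$glmnet.fit, s = pick)[-1, 1]
  if (!any(abs(cf) > nz_tol)) {
    nz <- cv$nzero
    ok <- which(nz > 0)
    if (!length(ok)) stop("lasso path never retains a feature")
    pick <- min(cv$lambda[ok])
    cf <- stats::coef(cv$glmnet.fit, s = pick)[-1, 1]
  }
  sel <- names(cf)[abs(cf) > nz_tol]
  list(selected = sel, coefficients = cf[abs(cf) > nz_tol], lambda = pick,
       cv = data.frame(lambda = cv$lambda, cvm = cv$cvm, nzero = as.integer(cv$nzero)))
}

#' Grid-searched gradient-boosted regression
#'
#' Evaluates every hyperparameter cell with k-fold cross-validation on the
#' training rows (mean validation RMSE at the final boosting round) and
#' refits the best cell on all training rows.
#'
#' @param train feature table with the target column.
#' @param selected feature names to use.
#' @param gbt_grid hyperparameter grid (see [experiment_config()]).
#' @param folds CV folds.
#' @param nrounds boosting rounds.
#' @param target target column name.
#' @param seed integer seed (fold assignment and boosting).
#' @return list with the fitted `booster`, `best_params`, `cv_table`
#'   (per-cell mean validation RMSE), `selected`, `nrounds`.
#' @export
train_gbt <- function(train, selected, gbt_grid, folds = 5, nrounds = 100,
                      target = "cyclo_S", seed = 1L) {
  if (!nrow(gbt_grid)) stop("empty hyperparameter grid")
  if (!all(selected %in% names(train)))
    stop("selected features missing from training table")
  x <- as.matrix(train[, selected, drop = FALSE])
  y <- train[[target]]
  dtrain <- xgboost::xgb.DMatrix(x, label = y)
  foldid <- .make_foldid(nrow(x), folds, seed)
  fold_list <- split(seq_len(nrow(x)), foldid)
  cv_rmse <- numeric(nrow(gbt_grid))
  for (i in seq_len(nrow(gbt_grid))) {
    g <- gbt_grid[i, ]
    params <- list(objective = "reg:squarederror", eta = g$eta,
                   max_depth = g$max_depth, subsample = g$subsample,
                   lambda = g$lambda, nthread = 1, seed = as.integer(seed))
    cv <- xgboost::xgb.cv(params = params, data = dtrain, nrounds = nrounds,
                          folds = fold_list, verbose = 0)
    cv_rmse[i] <- utils::tail(cv$evaluation_log$test_rmse_mean, 1)
  }
  best <- which.min(cv_rmse)
  g <- gbt_grid[best, ]
  params <- list(objective = "reg:squarederror", eta = g$eta,
                 max_depth = g$max_depth, subsample = g$subsample,
                 lambda = g$lambda, nthread = 1, seed = as.integer(seed))
  booster <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = nrounds, verbose = 0)
  list(booster = booster, best_params = as.list(g),
       cv_table = cbind(gbt_grid, cv_rmse = cv_rmse),
       selected = selected, nrounds = nrounds)
}

#' Regression error metrics
#'
#' Mean absolute error, mean squared error, its square root, the coefficient
#' of determination, and the percentage of predictions within 0.50 D of the
#' truth.
#'
#' @param pred,truth equal-length numeric vectors, D.
#' @return list with `mae`, `mse`, `rmse`, `r2`, `pct_within_half_D`, `n`.
#' @export
evaluate_predictions <- function(pred, truth) {
  stopifnot(length(pred) == length(truth), length(truth) > 0)
  e <- pred - truth
  mse <- mean(e^2)
  sst <- sum((truth - mean(truth))^2)
  list(mae = mean(abs(e)), mse = mse, rmse = sqrt(mse),
       r2 = if (sst > 0) 1 - sum(e^2) / sst else NA_real_,
       pct_within_half_D = 100 * mean(abs(e) <= 0.50), n = length(truth))
}

#' Paired t-test of predictions against truth
#'
#' Two-sided paired Student t-test on the differences `pred - truth`:
#' `t = mean / (sd / sqrt(n))` with `n - 1` degrees of freedom.
#'
#' @param pred,truth equal-length numeric vectors (`n >= 2`).
#' @return list with `mean_diff`, `sd`, `n`, `t`, `p`, `df`, and
#'   `degenerate` (TRUE when the differences have zero variance, in which
#'   case `t` and `p` are undefined).
#' @export
paired_ttest <- function(pred, truth) {
  stopifnot(length(pred) == length(truth), length(truth) >= 2)
  paired_ttest_summary(mean(pred - truth), stats::sd(pred - truth),
                       length(truth))
}

#' Paired t-test from summary statistics
#'
#' Replays a paired t-test from its printed summary (mean difference, SD of
#' differences, sample size).
#'
#' @param mean_diff mean of the paired differences.
#' @param sd standard deviation of the differences.
#' @param n number of pairs.
#' @return as [paired_ttest()].
#' @export
paired_ttest_summary <- function(mean_diff, sd, n) {
  if (sd == 0)
    return(list(mean_diff = mean_diff, sd = 0, n = n, t = NA_real_,
                p = NA_real_, df = n - 1, degenerate = TRUE))
  t <- mean_diff / (sd / sqrt(n))
  list(mean_diff = mean_diff, sd = sd, n = n, t = t,
       p = 2 * stats::pt(-abs(t), df = n - 1), df = n - 1, degenerate = FALSE)
}

#' Bland-Altman 95% limits of agreement
#'
#' `mean_diff +/- 1.96 * sd(differences)`.
#'
#' @param pred,truth equal-length numeric vectors (`n >= 2`), or set
#'   `sd_diff` directly with `pred` as the mean difference to replay printed
#'   summaries via [loa_from_summary()].
#' @return list with `mean_diff`, `half_width`, `lower`, `upper`.
#' @export
limits_of_agreement <- function(pred, truth) {
  stopifnot(length(pred) == length(truth), length(truth) >= 2)
  loa_from_summary(mean(pred - truth), stats::sd(pred - truth))
}

#' Limits of agreement from summary statistics
#'
#' @param mean_diff mean difference.
#' @param sd_diff standard deviation of the differences.
#' @return as [limits_of_agreement()].
#' @export
loa_from_summary <- function(mean_diff, sd_diff) {
  hw <- 1.96 * sd_diff
  list(mean_diff = mean_diff, half_width = hw,
       lower = mean_diff - hw, upper = mean_diff + hw)
}

#' Age-subgroup evaluation
#'
#' Applies [evaluate_predictions()] within each age bin. An eye belongs to
#' the first interval `[lo, hi]` containing its floored age; bins holding
#' fewer than five eyes are flagged.
#'
#' @param pred,truth numeric vectors.
#' @param age ages in years, same length.
#' @param age_bins list of `c(lo, hi)` inclusive intervals.
#' @return named list per bin: the metrics plus `flagged` (TRUE when
#'   `n < 5`; empty bins return `NULL` metrics and are flagged).
#' @export
subgroup_eval <- function(pred, truth, age,
                          age_bins = list(c(4, 8), c(9, 15))) {
  stopifnot(length(pred) == length(truth), length(age) == length(truth))
  out <- list()
  for (b in age_bins) {
    nm <- sprintf("%g-%g", b[1], b[2])
    in_bin <- floor(age) >= b[1] & floor(age) <= b[2]
    if (!any(in_bin)) {
      out[[nm]] <- list(metrics = NULL, n = 0L, flagged = TRUE)
    } else {
      m <- evaluate_predictions(pred[in_bin], truth[in_bin])
      out[[nm]] <- list(metrics = m, n = sum(in_bin), flagged = m$n < 5)
    }
  }
  out
}

#' Baseline regressors on the screened features
#'
#' Ordinary least squares and an RBF-kernel support-vector regressor (cost
#' tuned by k-fold CV on the training rows) fitted on the same selected
#' features and evaluated on the same test split as the boosted model.
#'
#' @param train,test feature tables with the target column.
#' @param selected feature names.
#' @param target target column name.
#' @param folds CV folds for SVM cost tuning.
#' @param cost_grid candidate SVM costs.
#' @param seed integer seed.
#' @return list with `linear` and `svm`, each holding `metrics` (see
#'   [evaluate_predictions()]) and `pred`; the SVM entry also reports the
#'   chosen `cost`.
#' @export
baseline_models <- function(train, test, selected, target = "cyclo_S",
                            folds = 5, cost_grid = c(0.1, 1, 10), seed = 1L) {
  fml <- stats::reformulate(sprintf("`%s`", selected), response = target)
  lin <- stats::lm(fml, data = train)
  pred_lin <- unname(stats::predict(lin, newdata = test))

  foldid <- .make_foldid(nrow(train), folds, seed)
  cv_rmse <- vapply(cost_grid, function(cc) {
    errs <- vapply(seq_len(folds), function(f) {
      fit <- e1071::svm(fml, data = train[foldid != f, ], kernel = "radial",
                        cost = cc)
      mean((stats::predict(fit, newdata = train[foldid == f, ]) -
              train[[target]][foldid == f])^2)
    }, numeric(1))
    sqrt(mean(errs))
  }, numeric(1))
  cost <- cost_grid[which.min(cv_rmse)]
  sv <- e1071::svm(fml, data = train, kernel = "radial", cost = cost)
  pred_svm <- unname(stats::predict(sv, newdata = test))

  list(linear = list(metrics = evaluate_predictions(pred_lin, test[[target]]),
                     pred = pred_lin),
       svm = list(metrics = evaluate_predictions(pred_svm, test[[target]]),
                  pred = pred_svm, cost = cost,
                  cv = data.frame(cost = cost_grid, cv_rmse = cv_rmse)))
}
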