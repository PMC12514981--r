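#' Run the full four-group prediction experiment
#'
#' Fits every requested model group ([fit_cyclo()]) on one shared train/test
#' split, so the groups are compared on identical held-out eyes, and
#' collects the comparison battery into a report.
#'
#' @param records raw per-eye records including `cyclo_S`.
#' @param config an [experiment_config()].
#' @param constants an [optical_constants()] object.
#' @return an object of class `cyclo_report`: per-group fits, a comparison
#'   table, and a replay bundle (seed, configuration, selected features).
#' @export
run_experiment <- function(records, config = experiment_config(),
                           constants = optical_constants()) {
  split <- split_train_test(records, config$test_fraction,
                            grouped = config$subject_grouped_split,
                            seed = config$seed)
  fits <- lapply(config$groups, function(g)
    fit_cyclo(records, g, config, split = split, constants = constants))
  names(fits) <- config$groups
  rep <- list(fits = fits, config = config, split = split,
              replay = list(seed = config$seed,
                            selected = lapply(fits, function(f) f$gbt$selected),
                            best_params = lapply(fits, function(f) f$gbt$best_params)))
  class(rep) <- "cyclo_report"
  rep
}

#' Machine-readable report table
#'
#' Flattens a [run_experiment()] report into a long key-value data.frame
#' (`group`, `metric`, `value`) covering the error metrics, paired t-test,
#' limits of agreement, age subgroups and baseline models. Writing this
#' table to CSV and reading it back reproduces the report's numbers exactly.
#'
#' @param x a `cyclo_report`.
#' @param ... unused.
#' @return a data.frame with columns `group`, `metric`, `value`.
#' @export
as.data.frame.cyclo_report <- function(x, ...) {
  rows <- list()
  add <- function(group, metric, value)
    rows[[length(rows) + 1]] <<- data.frame(group = group, metric = metric,
                                            value = as.numeric(value))
  for (g in names(x$fits)) {
    f <- x$fits[[g]]
    m <- f$metrics
    for (nm in c("mae", "mse", "rmse", "r2", "pct_within_half_D", "n"))
      add(g, nm, m[[nm]])
    tt <- f$ttest
    for (nm in c("mean_diff", "sd", "t", "p")) add(g, paste0("ttest_", nm), tt[[nm]])
    add(g, "loa_half_width", f$loa$half_width)
    add(g, "loa_lower", f$loa$lower)
    add(g, "loa_upper", f$loa$upper)
    for (nm in names(f$subgroups)) {
      sg <- f$subgroups[[nm]]
      if (!is.null(sg$metrics)) {
        add(g, sprintf("age%s_rmse", nm), sg$metrics$rmse)
        add(g, sprintf("age%s_mae", nm), sg$metrics$mae)
        add(g, sprintf("age%s_n", nm), sg$n)
      }
    }
    add(g, "baseline_linear_rmse", f$baselines$linear$metrics$rmse)
    add(g, "baseline_linear_r2", f$baselines$linear$metrics$r2)
    add(g, "baseline_svm_rmse", f$baselines$svm$metrics$rmse)
    add(g, "baseline_svm_r2", f$baselines$svm$metrics$r2)
  }
  do.call(rbind, rows)
}

#' @method print cyclo_report
#' @export
print.cyclo_report <- function(x, ...) {
  cat("Cycloplegic sphere prediction experiment\n")
  cat(sprintf("  %d groups on a shared %d/%d split (seed %d)\n\n",
              length(x$fits), length(x$split$train_idx),
              length(x$split$test_idx), x$config$seed))
  tab <- t(vapply(x$fits, function(f)
    c(MAE = f$metrics$mae, MSE = f$metrics$mse, RMSE = f$metrics$rmse,
      r2 = f$metrics$r2, `within0.5D%` = f$metrics$pct_within_half_D),
    numeric(5)))
  print(round(tab, 3))
  cat("\nPaired t-test and 95% limits of agreement (predicted - true):\n")
  tab2 <- t(vapply(x$fits, function(f)
    c(MD = f$ttest$mean_diff, SD = f$ttest$sd, t = f$ttest$t, p = f$ttest$p,
      LOA_half = f$loa$half_width), numeric(5)))
  print(round(tab2, 3))
  invisible(x)
}
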