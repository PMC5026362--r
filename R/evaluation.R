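# The three simulated prediction tasks -- missing-data imputation (4-bin
# rotation within each PEF), future forecasting (each PEF's last test
# withheld), and new-patient generalization (whole PEFs withheld) -- plus
# MSE scoring and the forecast-horizon error-gap regression.

#' Random 4-bin imputation folds within each PEF
#'
#' Each PEF's rows are randomly split into `n_bins` bins whose sizes differ
#' by at most one (larger bins first in permutation order); over the
#' rotation each bin serves as the missing data exactly once.  Every PEF
#' must have at least `n_bins` rows, which the cohort filters guarantee.
#'
#' @param dataset a `pef_dataset`.
#' @param seed integer seed (deterministic folds).
#' @param n_bins number of bins (default 4).
#' @return Class `fold_spec`: `task = "imputation"`, `bin` (integer vector
#'   aligned with the dataset rows), `n_bins`, `seed`.
#' @export
make_imputation_folds <- function(dataset, seed, n_bins = 4L) {
  v <- dataset_views(dataset)
  counts <- tabulate(v$g)
  if (any(counts < n_bins))
    stop("every PEF needs at least ", n_bins, " rows; PEF ",
         levels(v$g)[which(counts < n_bins)[1]], " has fewer")
  bin <- integer(nrow(dataset))
  with_preserved_seed(seed, {
    for (p in seq_len(nlevels(v$g))) {
      idx <- which(as.integer(v$g) == p)
      n <- length(idx)
      sizes <- rep(n %/% n_bins, n_bins) + (seq_len(n_bins) <= n %% n_bins)
      bin[idx[sample(n)]] <- rep(seq_len(n_bins), times = sizes)
    }
  })
  structure(list(task = "imputation", bin = bin, n_bins = n_bins,
                 seed = seed),
            class = "fold_spec")
}

#' Forecast split: withhold each PEF's last test
#'
#' The maximal-age row of every PEF (age ties broken by last stable
#' position) becomes the test set; all earlier rows train the models.  The
#' forecast horizon -- years between the last training test and the
#' withheld one -- is recorded per PEF.
#'
#' @param dataset a `pef_dataset`.
#' @return Class `fold_spec`: `task = "forecast"`, `is_test` logical
#'   vector, `horizon` named numeric vector (years, by PEF key).
#' @export
make_forecast_split <- function(dataset) {
  v <- dataset_views(dataset)
  is_test <- logical(nrow(dataset))
  horizon <- numeric(nlevels(v$g))
  names(horizon) <- levels(v$g)
  for (p in seq_len(nlevels(v$g))) {
    idx <- which(as.integer(v$g) == p)
    ages <- dataset$age_years[idx]
    last <- idx[max(which(ages == max(ages)))]
    is_test[last] <- TRUE
    horizon[p] <- dataset$age_years[last] - max(ages[ages < max(ages)],
                                                ages[1])
  }
  structure(list(task = "forecast", is_test = is_test, horizon = horizon),
            class = "fold_spec")
}

#' New-patient split: withhold whole PEFs
#'
#' PEFs are sampled without replacement until their rows make up at least
#' `test_fraction` of all rows; the split is at PEF level, so no PEF ever
#' straddles train and test.
#'
#' @param dataset a `pef_dataset`.
#' @param test_fraction target fraction of rows withheld (default 0.22).
#' @param seed integer seed.
#' @return Class `fold_spec`: `task = "new_patient"`, `is_test` logical
#'   vector, `test_keys`.
#' @export
make_newpatient_split <- function(dataset, test_fraction = 0.22, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  v <- dataset_views(dataset)
  keys <- levels(v$g)
  counts <- tabulate(v$g)
  target <- test_fraction * nrow(dataset)
  test_keys <- with_preserved_seed(seed, {
    ord <- sample(length(keys))
    cum <- cumsum(counts[ord])
    n_take <- which(cum >= target)[1]
    if (is.na(n_take) || n_take >= length(keys))
      stop("cannot reach test fraction ", test_fraction,
           " while keeping a non-empty training set")
    keys[ord[seq_len(n_take)]]
  })
  structure(list(task = "new_patient", is_test = keys[v$g] %in% test_keys,
                 test_keys = test_keys, seed = seed),
            class = "fold_spec")
}

#' Mean squared prediction error, per fold and averaged
#'
#' Per-fold MSE is the mean squared difference between predicted and
#' observed thresholds within the fold; the task score is the unweighted
#' mean over folds, with its square root reported as the average dB margin
#' of error.
#'
#' @param predictions data.frame with `predicted_db`, `observed_db`, and
#'   optionally `fold` (absent = single fold).
#' @return Class `task_result`: `fold_mse`, `mse`, `rmse`, `n`,
#'   `predictions`.
#' @export
score_mse <- function(predictions) {
  if (nrow(predictions) == 0) stop("no predictions to score")
  fold <- predictions$fold
  if (is.null(fold)) fold <- rep(1L, nrow(predictions))
  sq <- (predictions$predicted_db - predictions$observed_db)^2
  fold_mse <- tapply(sq, fold, mean)
  if (any(!is.finite(fold_mse))) stop("empty fold in predictions")
  mse <- mean(fold_mse)
  structure(list(fold_mse = as.numeric(fold_mse), mse = mse,
                 rmse = sqrt(mse), n = nrow(predictions),
                 predictions = predictions),
            class = "task_result")
}

#' @export
print.task_result <- function(x, ...) {
  cat("MSE:", round(x$mse, 2), "(RMSE", round(x$rmse, 2), "dB) over",
      length(x$fold_mse), "fold(s),", x$n, "predictions\n")
  invisible(x)
}

#' Forecast error-gap regression on horizon
#'
#' Regresses the per-PEF difference in absolute forecast error between the
#' mixed-effects and mixture models, `|err_mixed| - |err_mixture|`, on the
#' forecast horizon (years), controlling for the observed threshold of the
#' withheld test.  A positive horizon coefficient means the mixed model's
#' error grows faster with forecast distance than the mixture's -- the
#' within-individual drift signature.
#'
#' @param gap_data data.frame with one row per PEF: `abs_err_mixed`,
#'   `abs_err_mixture`, `horizon_years`, `observed_db`.
#' @return data.frame of coefficients: term, estimate, se, t, p.
#' @export
error_gap_regression <- function(gap_data) {
  needed <- c("abs_err_mixed", "abs_err_mixture", "horizon_years",
              "observed_db")
  missing <- setdiff(needed, names(gap_data))
  if (length(missing))
    stop("gap_data is missing columns: ", paste(missing, collapse = ", "))
  if (nrow(gap_data) < 3) stop("error-gap regression needs at least 3 PEFs")
  fit <- stats::lm(I(abs_err_mixed - abs_err_mixture) ~ horizon_years +
                     observed_db, data = gap_data)
  cf <- summary(fit)$coefficients
  data.frame(term = rownames(cf), estimate = cf[, 1], se = cf[, 2],
             t = cf[, 3], p = cf[, 4], row.names = NULL)
}

# fit one model spec on a training set and predict a test set
fit_predict_one <- function(spec, train, test, condition, seed) {
  if (spec$model == "ols") {
    fit <- fit_ols(train)
    data.frame(predicted_db = predict_baseline(fit, test$pef_key, test),
               observed_db = test$threshold_db,
               pef_key = test$pef_key, stringsAsFactors = FALSE)
  } else if (spec$model == "mixed") {
    fit <- fit_mixed(train)
    pred <- predict_baseline(fit, test$pef_key, test)
    data.frame(predicted_db = as.numeric(pred),
               observed_db = test$threshold_db,
               pef_key = test$pef_key,
               fallback = attr(pred, "fallback"),
               stringsAsFactors = FALSE)
  } else {
    fit <- fit_mixture(train, spec$k, seed = seed,
                       n_starts = spec$n_starts %||% 5)
    mode <- if (spec$new_pef) "new_pef" else "known_pef"
    predict_for_task(fit$model, fit$responsibilities, test, mode = mode,
                     condition = condition)
  }
}

#' Run one of the three simulated prediction tasks
#'
#' Builds the task's split(s), trains every requested model on the
#' training rows only, predicts the withheld rows under the task's
#' membership protocol (training responsibilities for tasks where the PEF
#' was seen; Bayes-rule inference with no retraining for new PEFs; the
#' mixed model's fixed-effects fallback for new PEFs), and scores MSE.
#' The mixture is fitted for every `k` in `k_values`, giving the
#' MSE-vs-k curve.
#'
#' For the forecasting task the per-PEF error-gap table (absolute error of
#' the mixed model and of the mixture at the largest `k`, the forecast
#' horizon, and the observed threshold) and its [error_gap_regression()]
#' are included.
#'
#' @param dataset a prepared `pef_dataset`.
#' @param task `"imputation"`, `"forecast"`, or `"new_patient"`.
#' @param models subset of `c("ols", "mixed", "mixture")`.
#' @param k_values mixture cluster counts to evaluate.
#' @param seed integer seed for splits and EM initializations.
#' @param test_fraction new-patient task: fraction of rows withheld.
#' @param condition new-PEF conditioning protocol (see
#'   [predict_for_task()]).
#' @param n_starts EM restarts per mixture fit.
#' @return Class `task_comparison`: `task`, `summary` (model, k, mse,
#'   rmse), `fold_mse`, `predictions`, and for the forecast task
#'   `gap_data` + `error_gap`.
#' @export
run_task <- function(dataset,
                     task = c("imputation", "forecast", "new_patient"),
                     models = c("ols", "mixed", "mixture"),
                     k_values = 1:4, seed = 1L, test_fraction = 0.22,
                     condition = "loo", n_starts = 5) {
  task <- match.arg(task)
  models <- match.arg(models, several.ok = TRUE)

  splits <- switch(task,
    imputation = {
      fs <- make_imputation_folds(dataset, seed)
      lapply(seq_len(fs$n_bins), function(b)
        list(train = dataset[fs$bin != b, , drop = FALSE],
             test = dataset[fs$bin == b, , drop = FALSE]))
    },
    forecast = {
      fs <- make_forecast_split(dataset)
      list(list(train = dataset[!fs$is_test, , drop = FALSE],
                test = dataset[fs$is_test, , drop = FALSE],
                horizon = fs$horizon))
    },
    new_patient = {
      fs <- make_newpatient_split(dataset, test_fraction, seed)
      list(list(train = dataset[!fs$is_test, , drop = FALSE],
                test = dataset[fs$is_test, , drop = FALSE]))
    })

  specs <- list()
  for (m in models) {
    if (m == "mixture") {
      for (k in k_values)
        specs[[paste0("mixture_k", k)]] <-
          list(model = "mixture", k = k, new_pef = task == "new_patient",
               n_starts = n_starts)
    } else {
      specs[[m]] <- list(model = m)
    }
  }

  all_pred <- list()
  summary_rows <- list()
  fold_rows <- list()
  for (sn in names(specs)) {
    preds <- list()
    for (f in seq_along(splits)) {
      p <- fit_predict_one(specs[[sn]], splits[[f]]$train, splits[[f]]$test,
                           condition, seed = seed + 31L * f + specs[[sn]]$k %||% 0L)
      p$fold <- f
      preds[[f]] <- p
    }
    common <- c("pef_key", "observed_db", "predicted_db", "fold")
    ptab <- do.call(rbind, lapply(preds, function(p) p[common]))
    res <- score_mse(ptab)
    summary_rows[[sn]] <- data.frame(
      model = specs[[sn]]$model, k = specs[[sn]]$k %||% NA_integer_,
      mse = res$mse, rmse = res$rmse, stringsAsFactors = FALSE)
    fold_rows[[sn]] <- data.frame(
      model = specs[[sn]]$model, k = specs[[sn]]$k %||% NA_integer_,
      fold = seq_along(res$fold_mse), mse = res$fold_mse,
      stringsAsFactors = FALSE)
    all_pred[[sn]] <- ptab
  }

  out <- list(task = task,
              summary = do.call(rbind, c(summary_rows,
                                         make.row.names = FALSE)),
              fold_mse = do.call(rbind, c(fold_rows,
                                          make.row.names = FALSE)),
              predictions = all_pred,
              seed = seed)

  if (task == "forecast" && all(c("mixed", "mixture") %in% models)) {
    k_gap <- max(k_values)
    me <- all_pred[["mixed"]]
    mo <- all_pred[[paste0("mixture_k", k_gap)]]
    horizon <- splits[[1]]$horizon
    gap_data <- data.frame(
      pef_key = me$pef_key,
      abs_err_mixed = abs(me$predicted_db - me$observed_db),
      abs_err_mixture = abs(mo$predicted_db[match(me$pef_key, mo$pef_key)] -
                              mo$observed_db[match(me$pef_key, mo$pef_key)]),
      horizon_years = horizon[me$pef_key],
      observed_db = me$observed_db,
      stringsAsFactors = FALSE)
    out$gap_data <- gap_data
    out$error_gap <- error_gap_regression(gap_data)
    out$gap_k <- k_gap
  }
  class(out) <- "task_comparison"
  out
}

#' @export
print.task_comparison <- function(x, ...) {
  cat("Task:", x$task, "\n")
  print(x$summary, row.names = FALSE)
  if (!is.null(x$error_gap)) {
    cat("\nError-gap regression (|err_mixed| - |err_mixture|, mixture k =",
        x$gap_k, "):\n")
    print(x$error_gap, row.names = FALSE)
  }
  invisible(x)
}
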