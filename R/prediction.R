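# Prediction engine of the mixture model: posterior-weighted cluster
# predictions for known PEFs, and Bayes-rule membership inference for PEFs
# never seen in training -- no retraining, only the fitted parameters.

#' Infer cluster membership of a PEF by Bayes rule
#'
#' Posterior over clusters given the PEF's observed rows:
#' `p(cluster = k | rows)` is proportional to `pi_k` times the joint
#' likelihood of the rows under cluster k, normalized in log space.  With
#' no observations the posterior is the mixing prior.  The model is never
#' modified -- generalization to a new patient needs no retraining.
#'
#' @param model a fitted `mor_model`.
#' @param rows observed rows of one PEF (may be empty).
#' @return Class `membership_posterior`: `probs` (k-vector summing to 1)
#'   and `n_obs_used`.
#' @export
infer_membership <- function(model, rows) {
  if (is.null(rows) || nrow(rows) == 0) {
    probs <- model$mixing
    n <- 0L
  } else {
    ll <- vapply(seq_len(model$k),
                 function(kk) pef_log_likelihood(model, rows, kk),
                 numeric(1))
    a <- log(model$mixing) + ll
    probs <- exp(a - logsumexp(a))
    n <- nrow(rows)
  }
  structure(list(probs = probs, n_obs_used = n),
            class = "membership_posterior")
}

#' Posterior-weighted threshold prediction
#'
#' Each cluster's regression prediction `beta_k . x` is weighted by the
#' PEF's posterior probability of belonging to that cluster; the result is
#' a convex combination of the cluster predictions.
#'
#' @param model a `mor_model`.
#' @param posterior a `membership_posterior` or bare probability k-vector.
#' @param rows rows with design columns.
#' @return Numeric vector of predicted thresholds, dB.
#' @export
predict_threshold <- function(model, posterior, rows) {
  probs <- if (inherits(posterior, "membership_posterior"))
    posterior$probs else as.numeric(posterior)
  if (length(probs) != model$k)
    stop("posterior length ", length(probs), " does not match k = ", model$k)
  drop(design_matrix(rows) %*% t(model$betas) %*% probs)
}

#' Predict a test table under a task's membership protocol
#'
#' Known-PEF mode (imputation, forecasting): a test PEF's posterior is
#' looked up from its training responsibilities; a PEF absent from
#' training falls through to the new-PEF path and is flagged.  New-PEF
#' mode (new-patient generalization): the posterior comes from
#' [infer_membership()] on conditioning rows of the same PEF --
#' `"loo"` conditions each prediction on the PEF's other test rows,
#' `"all"` on all its rows, `"prefix"` only on rows earlier in age.  A
#' prediction with zero conditioning rows uses the mixing prior and is
#' flagged.  Model parameters are never updated.
#'
#' @param model a fitted `mor_model`.
#' @param train_resp training responsibility matrix (PEF keys as
#'   rownames); may be `NULL` in new-PEF mode.
#' @param test_data a `pef_dataset` of rows to predict.
#' @param mode `"known_pef"` or `"new_pef"`.
#' @param condition conditioning protocol for new-PEF mode.
#' @return data.frame: `pef_key`, `age_years`, `observed_db`,
#'   `predicted_db`, `mode` (path actually used per row), `fallback`,
#'   `prior_only`, `n_cond`, and posterior columns `p1..pk`.
#' @export
predict_for_task <- function(model, train_resp, test_data,
                             mode = c("known_pef", "new_pef"),
                             condition = c("loo", "all", "prefix")) {
  mode <- match.arg(mode)
  condition <- match.arg(condition)
  stopifnot(inherits(model, "mor_model"))
  keys <- test_data$pef_key
  if (is.null(keys)) stop("test_data must carry pef_key; see code_pefs()")
  groups <- split(seq_len(nrow(test_data)), factor(keys, unique(keys)))

  k <- model$k
  n <- nrow(test_data)
  post <- matrix(NA_real_, n, k)
  used_mode <- character(n)
  fallback <- logical(n)
  prior_only <- logical(n)
  n_cond <- integer(n)

  for (key in names(groups)) {
    idx <- groups[[key]]
    rows <- test_data[idx, , drop = FALSE]
    known <- mode == "known_pef" && !is.null(train_resp) &&
      key %in% rownames(train_resp)
    if (known) {
      post[idx, ] <- matrix(train_resp[key, ], length(idx), k, byrow = TRUE)
      used_mode[idx] <- "known_pef"
      n_cond[idx] <- NA_integer_
    } else {
      fallback[idx] <- mode == "known_pef"
      used_mode[idx] <- "new_pef"
      if (condition == "all") {
        mp <- infer_membership(model, rows)
        post[idx, ] <- matrix(mp$probs, length(idx), k, byrow = TRUE)
        n_cond[idx] <- mp$n_obs_used
      } else {
        for (j in seq_along(idx)) {
          cond_rows <- switch(condition,
            loo = rows[-j, , drop = FALSE],
            prefix = rows[seq_len(j - 1L), , drop = FALSE])
          mp <- infer_membership(model, cond_rows)
          post[idx[j], ] <- mp$probs
          n_cond[idx[j]] <- mp$n_obs_used
          prior_only[idx[j]] <- mp$n_obs_used == 0L
        }
      }
    }
  }

  pred <- rowSums((design_matrix(test_data) %*% t(model$betas)) * post)
  out <- data.frame(pef_key = keys,
                    age_years = test_data$age_years,
                    observed_db = test_data$threshold_db,
                    predicted_db = pred,
                    mode = used_mode,
                    fallback = fallback,
                    prior_only = prior_only,
                    n_cond = n_cond,
                    stringsAsFactors = FALSE)
  colnames(post) <- paste0("p", seq_len(k))
  cbind(out, post)
}
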