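# Comparison predictors: pooled OLS and a linear mixed-effects model with
# PEF-level random intercept and slopes.  The mixed model is estimated by
# REML via lme4; the prediction contract -- BLUP-adjusted predictions for
# seen PEFs, population fixed effects for unseen ones -- is implemented
# here so the new-patient fallback path is explicit.

#' Pooled ordinary least squares fit
#'
#' One set of population-level coefficients for
#' `threshold ~ 1 + log(age) + gender + log(diagnoses + 1)`.
#'
#' @param dataset rows with design columns and `threshold_db`.
#' @return Class `ols_model`: `beta` (4-vector), `sigma2` (maximum
#'   likelihood residual variance, dB^2), `se` (coefficient standard
#'   errors), `n`.
#' @export
fit_ols <- function(dataset) {
  X <- design_matrix(dataset)
  y <- dataset$threshold_db
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    dropped <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    stop("design is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  beta <- qr.coef(qrx, y)
  r <- y - drop(X %*% beta)
  n <- length(y)
  rss <- sum(r^2)
  se <- sqrt(diag(chol2inv(qr.R(qrx))) * rss / max(n - ncol(X), 1))
  structure(list(beta = beta, sigma2 = rss / n, se = se, n = n),
            class = "ols_model")
}

#' @export
print.ols_model <- function(x, ...) {
  cat("Pooled OLS fit (n =", x$n, ")\n")
  print(round(rbind(estimate = x$beta, se = x$se), 4))
  cat("residual variance:", round(x$sigma2, 3), "dB^2\n")
  invisible(x)
}

#' Linear mixed-effects fit with PEF-level random effects
#'
#' REML fit of the pooled regression with a PEF-specific random intercept
#' and random slopes for all predictors (unstructured covariance).  If that
#' fit fails or the random-effect covariance is singular -- common, since
#' gender is constant within a PEF -- the model is refitted with a random
#' intercept only, and the fallback is recorded.
#'
#' @param dataset a `pef_dataset` with design columns.
#' @param random `"full"` (intercept + all slopes) or `"intercept"`.
#' @return Class `mixed_model`: `beta_fixed` (4-vector), `random_cov`
#'   (4x4, zero rows/columns for absent terms), `blups` (P x 4 matrix of
#'   per-PEF deviations, keys as rownames), `sigma2`, `structure` actually
#'   used, `fallback` flag.
#' @export
fit_mixed <- function(dataset, random = c("full", "intercept")) {
  random <- match.arg(random)
  d <- as.data.frame(dataset)
  d$pef_key <- factor(d$pef_key, levels = unique(d$pef_key))
  if (nlevels(d$pef_key) < 2) stop("fit_mixed requires at least 2 PEFs")
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore")
  forms <- list(
    full = threshold_db ~ log_age + gender_f + log_diag +
      (1 + log_age + gender_f + log_diag | pef_key),
    intercept = threshold_db ~ log_age + gender_f + log_diag +
      (1 | pef_key))

  try_fit <- function(which) {
    tryCatch(
      suppressWarnings(suppressMessages(
        lme4::lmer(forms[[which]], data = d, REML = TRUE, control = ctrl))),
      error = function(e) NULL)
  }

  used <- random
  fit <- try_fit(used)
  fallback <- FALSE
  if (used == "full" &&
      (is.null(fit) || lme4::isSingular(fit, tol = 1e-4))) {
    used <- "intercept"
    fallback <- TRUE
    fit <- try_fit(used)
  }
  if (is.null(fit)) stop("mixed-effects fit failed for both structures")

  fe <- lme4::fixef(fit)
  term_map <- c("(Intercept)" = 1L, log_age = 2L, gender_f = 3L,
                log_diag = 4L)
  beta_fixed <- numeric(4L)
  names(beta_fixed) <- design_columns()
  beta_fixed[term_map[names(fe)]] <- fe

  vc <- lme4::VarCorr(fit)$pef_key
  random_cov <- matrix(0, 4, 4, dimnames = list(design_columns(),
                                                design_columns()))
  idx <- term_map[rownames(vc)]
  random_cov[idx, idx] <- as.matrix(vc)

  re <- lme4::ranef(fit)$pef_key
  blups <- matrix(0, nlevels(d$pef_key), 4L,
                  dimnames = list(levels(d$pef_key), design_columns()))
  blups[rownames(re), term_map[colnames(re)]] <- as.matrix(re)

  structure(
    list(beta_fixed = beta_fixed, random_cov = random_cov, blups = blups,
         sigma2 = stats::sigma(fit)^2, structure = used,
         fallback = fallback),
    class = "mixed_model")
}

#' @export
print.mixed_model <- function(x, ...) {
  cat("Mixed-effects fit (random structure:", x$structure,
      if (x$fallback) "[fallback]", ")\n")
  print(round(x$beta_fixed, 4))
  cat("random-effect SDs:",
      paste(round(sqrt(diag(x$random_cov)), 3), collapse = ", "),
      "| residual SD:", round(sqrt(x$sigma2), 3), "dB\n")
  invisible(x)
}

#' Predict thresholds from a baseline model
#'
#' OLS predicts `beta . x` for every row.  The mixed model predicts
#' `(beta + B_pef) . x` for a PEF seen in training and falls back to the
#' population fixed effects `beta . x` for an unseen PEF -- at prediction
#' time a mixed model has no individual information about a new patient.
#'
#' @param model an `ols_model` or `mixed_model`.
#' @param pef_keys character vector of PEF keys, one per row (ignored by
#'   OLS).
#' @param rows data rows with design columns.
#' @return Numeric vector of predicted thresholds (dB); for the mixed
#'   model, attribute `"fallback"` is a logical vector marking rows
#'   predicted with fixed effects only.
#' @export
predict_baseline <- function(model, pef_keys, rows) {
  UseMethod("predict_baseline")
}

#' @export
predict_baseline.ols_model <- function(model, pef_keys, rows) {
  drop(design_matrix(rows) %*% model$beta)
}

#' @export
predict_baseline.mixed_model <- function(model, pef_keys, rows) {
  X <- design_matrix(rows)
  base <- drop(X %*% model$beta_fixed)
  seen <- pef_keys %in% rownames(model$blups)
  adj <- numeric(nrow(X))
  if (any(seen)) {
    B <- model$blups[pef_keys[seen], , drop = FALSE]
    adj[seen] <- rowSums(X[seen, , drop = FALSE] * B)
  }
  out <- base + adj
  attr(out, "fallback") <- !seen
  out
}
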