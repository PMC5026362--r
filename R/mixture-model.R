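# Grouped mixture of linear regressions: K clusters sharing the regression
# form threshold ~ N(beta_k . x, sigma2_k), with the constraint that all
# observations of one PEF belong to the same latent cluster.  Fitted by EM
# with PEF-level responsibilities; membership for unseen PEFs is inferred
# by Bayes rule from the fitted parameters (see infer_membership()).

logsumexp <- function(a) {
  m <- max(a)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(a - m)))
}

new_mor_model <- function(betas, sigma2s, mixing, se = NULL,
                          pruned = integer(0)) {
  betas <- as.matrix(betas)
  colnames(betas) <- design_columns()
  structure(
    list(k = nrow(betas), betas = betas, sigma2s = as.numeric(sigma2s),
         mixing = as.numeric(mixing), se = se, pruned = pruned,
         column_names = design_columns()),
    class = "mor_model")
}

#' @export
print.mor_model <- function(x, ...) {
  cat("Mixture of regressions: k =", x$k, "\n")
  tab <- cbind(x$betas, sigma = sqrt(x$sigma2s), mixing = x$mixing)
  rownames(tab) <- paste0("cluster", seq_len(x$k))
  print(round(tab, 3))
  if (length(x$pruned))
    cat("pruned clusters (pre-sort indices):",
        paste(x$pruned, collapse = ", "), "\n")
  invisible(x)
}

# internal: P x k matrix of per-PEF log-likelihoods under each cluster
pef_loglik_matrix <- function(model, X, y, g) {
  k <- model$k
  ll <- matrix(0, nlevels(g), k, dimnames = list(levels(g), NULL))
  for (kk in seq_len(k)) {
    mu <- drop(X %*% model$betas[kk, ])
    rowll <- stats::dnorm(y, mu, sqrt(model$sigma2s[kk]), log = TRUE)
    ll[, kk] <- rowsum(rowll, g)[levels(g), 1]
  }
  ll
}

#' Log-likelihood of one PEF's observations under one cluster
#'
#' Sum over the PEF's rows of the Gaussian log-density of the observed
#' threshold given the cluster's regression mean and variance.
#'
#' @param model a `mor_model`.
#' @param rows the PEF's rows (with design columns and `threshold_db`).
#' @param cluster cluster index in `1..k`.
#' @return The log-density (finite for positive cluster variance).
#' @export
pef_log_likelihood <- function(model, rows, cluster) {
  if (nrow(rows) == 0) stop("pef_log_likelihood requires at least one row")
  if (cluster < 1 || cluster > model$k) stop("cluster index out of range")
  X <- design_matrix(rows)
  mu <- drop(X %*% model$betas[cluster, ])
  sum(stats::dnorm(rows$threshold_db, mu, sqrt(model$sigma2s[cluster]),
                   log = TRUE))
}

# grouping factor, design matrix and response for a pef_dataset
dataset_views <- function(dataset) {
  if (is.null(dataset$pef_key)) stop("dataset must carry pef_key; see code_pefs()")
  g <- factor(dataset$pef_key, levels = unique(dataset$pef_key))
  list(X = design_matrix(dataset), y = dataset$threshold_db, g = g)
}

#' E-step: posterior cluster membership per PEF
#'
#' Computes `r_ik = pi_k L_ik / sum_m pi_m L_im` in log space
#' (log-sum-exp), where `L_ik` is the joint Gaussian likelihood of all of
#' PEF i's rows under cluster k -- the rows of a PEF contribute jointly,
#' never individually.
#'
#' @param model a `mor_model`.
#' @param dataset a `pef_dataset` with design columns.
#' @return A `P x k` responsibility matrix (rows = PEFs, each summing
#'   to 1), with the observed-data log-likelihood in attribute `"loglik"`.
#' @export
e_step <- function(model, dataset) {
  v <- dataset_views(dataset)
  ll <- pef_loglik_matrix(model, v$X, v$y, v$g)
  a <- sweep(ll, 2, log(model$mixing), "+")
  m <- apply(a, 1, max)
  logz <- m + log(rowSums(exp(a - m)))
  resp <- exp(a - logz)
  attr(resp, "loglik") <- sum(logz)
  resp
}

#' M-step: weighted regression update of the mixture parameters
#'
#' Given PEF-level responsibilities, each cluster's coefficients solve a
#' weighted least-squares problem in which every row of a PEF carries its
#' PEF's responsibility; the cluster variance is the responsibility-weighted
#' mean squared residual (floored at `var_floor`), and the mixing
#' proportions are the PEF-level responsibility means (one multinomial draw
#' per PEF, not per row).
#'
#' @param dataset a `pef_dataset` with design columns.
#' @param resp `P x k` responsibility matrix with PEF keys as rownames
#'   (or aligned with the dataset's PEF order).
#' @param var_floor minimum cluster variance in dB^2.
#' @return A `mor_model`; coefficient standard errors come from the
#'   weighted-least-squares information matrix (approximate: membership
#'   uncertainty is ignored).
#' @export
m_step <- function(dataset, resp, var_floor = 1e-4) {
  v <- dataset_views(dataset)
  k <- ncol(resp)
  if (is.null(rownames(resp))) rownames(resp) <- levels(v$g)
  W <- resp[as.integer(v$g), , drop = FALSE]
  betas <- matrix(0, k, 4L)
  sigma2s <- numeric(k)
  se <- matrix(NA_real_, k, 4L)
  floor_hit <- logical(k)
  for (kk in seq_len(k)) {
    w <- W[, kk]
    sw <- sum(w)
    if (sw < 1e-10)
      stop("cluster ", kk, " has vanishing total responsibility; ",
           "weighted design is singular")
    XtWX <- crossprod(v$X, w * v$X)
    XtWy <- crossprod(v$X, w * v$y)
    beta <- tryCatch(solve(XtWX, XtWy),
                     error = function(e)
                       stop("weighted design singular for cluster ", kk,
                            ": ", conditionMessage(e)))
    r <- v$y - drop(v$X %*% beta)
    s2 <- sum(w * r^2) / sw
    if (s2 < var_floor) { s2 <- var_floor; floor_hit[kk] <- TRUE }
    betas[kk, ] <- beta
    sigma2s[kk] <- s2
    se[kk, ] <- sqrt(pmax(diag(solve(XtWX)), 0) * s2)
  }
  mod <- new_mor_model(betas, sigma2s, colMeans(resp), se = se)
  mod$var_floor_hit <- floor_hit
  mod
}

# reorder a fitted model's clusters (used for pruning and label alignment)
reorder_model <- function(model, ord) {
  model$betas <- model$betas[ord, , drop = FALSE]
  model$sigma2s <- model$sigma2s[ord]
  model$mixing <- model$mixing[ord] / sum(model$mixing[ord])
  if (!is.null(model$se)) model$se <- model$se[ord, , drop = FALSE]
  if (!is.null(model$var_floor_hit))
    model$var_floor_hit <- model$var_floor_hit[ord]
  model$k <- length(ord)
  model
}

# informed start: hard-assign PEFs by k-means on per-PEF trajectory
# summaries (mean residual from the pooled fit, crude threshold-vs-log-age
# slope).  Mixtures of trajectories are commonly initialized this way;
# purely random soft starts often converge to inferior local optima that
# split clusters along a minor covariate instead of the trajectory axes.
kmeans_init <- function(dataset, k) {
  v <- dataset_views(dataset)
  P <- nlevels(v$g)
  if (P <= k) return(NULL)
  beta0 <- tryCatch(qr.coef(qr(v$X), v$y), error = function(e) NULL)
  if (is.null(beta0)) return(NULL)
  resid <- v$y - drop(v$X %*% beta0)
  mean_resid <- rowsum(resid, v$g)[, 1] / tabulate(v$g)
  La <- v$X[, "log_age"]
  slope <- vapply(split(seq_along(La), v$g), function(idx) {
    x <- La[idx]; y <- v$y[idx]
    sxx <- sum((x - mean(x))^2)
    if (sxx < 1e-10) 0 else sum((x - mean(x)) * (y - mean(y))) / sxx
  }, numeric(1))
  feats <- scale(cbind(mean_resid, slope[levels(v$g)]))
  feats[!is.finite(feats)] <- 0
  km <- tryCatch(stats::kmeans(feats, centers = k, nstart = 5),
                 error = function(e) NULL)
  if (is.null(km)) return(NULL)
  resp <- matrix(1e-3 / (k - 1), P, k, dimnames = list(levels(v$g), NULL))
  resp[cbind(seq_len(P), km$cluster)] <- 1 - 1e-3
  resp
}

#' Fit the grouped mixture of regressions by EM
#'
#' Alternates [e_step()] and [m_step()] until the absolute change in
#' observed-data log-likelihood falls below `tol` or `max_iter` is reached,
#' over `n_starts` initializations: one informed start (PEFs hard-assigned
#' by k-means on per-PEF trajectory summaries) plus random PEF-level
#' responsibility draws from a symmetric Dirichlet(1); the start with the
#' best final log-likelihood wins.  After convergence, clusters holding fewer than
#' `prune_threshold` of PEFs by modal assignment are pruned (the
#' heuristic guard against overfitting into vanishing clusters) and the
#' E-step is re-run on the reduced model.  Clusters are reported sorted by
#' descending log-age coefficient.  `k = 1` is the pooled OLS solution,
#' exactly.
#'
#' @param dataset a `pef_dataset` with design columns.
#' @param k number of latent clusters (`>= 1`).
#' @param n_starts random restarts.
#' @param tol absolute log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations per start.
#' @param seed integer seed for the initializations (NULL = current RNG).
#' @param prune_threshold minimal modal share of PEFs a cluster must hold
#'   (default 1%).
#' @param var_floor minimum cluster variance, dB^2.
#' @return A list of class `mor_fit`: `model` (`mor_model`),
#'   `responsibilities` (`P x k` matrix, PEF keys as rownames), and `trace`
#'   (per-iteration log-likelihood of the winning start, iteration count,
#'   `converged` flag, seed, pruned cluster indices).  Non-convergence is
#'   reported via `trace$converged`, never an error.
#' @export
fit_mixture <- function(dataset, k, n_starts = 5, tol = 1e-6,
                        max_iter = 500, seed = NULL,
                        prune_threshold = 0.01, var_floor = 1e-4) {
  stopifnot(k >= 1, nrow(dataset) > 0)
  v <- dataset_views(dataset)
  P <- nlevels(v$g)

  if (k == 1) {
    ols <- fit_ols(dataset)
    model <- new_mor_model(matrix(ols$beta, 1), max(ols$sigma2, var_floor), 1,
                           se = matrix(ols$se, 1))
    resp <- matrix(1, P, 1, dimnames = list(levels(v$g), NULL))
    ll <- attr(e_step(model, dataset), "loglik")
    return(structure(
      list(model = model, responsibilities = resp,
           trace = list(loglik = ll, iterations = 0L, converged = TRUE,
                        seed = seed, pruned = integer(0))),
      class = "mor_fit"))
  }

  random_init <- function() {
    r0 <- matrix(stats::rexp(P * k), P, k)
    resp <- r0 / rowSums(r0)
    rownames(resp) <- levels(v$g)
    resp
  }

  # a singular weighted design mid-run (a cluster collapsing onto rows
  # that cannot identify all four coefficients) abandons that start's
  # refinement but keeps its last valid state; a singular initial M-step
  # discards the start
  run_em <- function(init_resp) {
    model <- tryCatch(m_step(dataset, init_resp, var_floor),
                      error = function(e) NULL)
    if (is.null(model)) return(NULL)
    ll_trace <- numeric(0)
    converged <- FALSE
    singular <- FALSE
    for (it in seq_len(max_iter)) {
      resp <- e_step(model, dataset)
      ll <- attr(resp, "loglik")
      ll_trace <- c(ll_trace, ll)
      if (it > 1 && abs(ll - ll_trace[it - 1]) < tol) {
        converged <- TRUE
        break
      }
      nxt <- tryCatch(m_step(dataset, resp, var_floor),
                      error = function(e) NULL)
      if (is.null(nxt)) { singular <- TRUE; break }
      model <- nxt
    }
    list(model = model, resp = resp, ll = ll_trace[length(ll_trace)],
         ll_trace = ll_trace, converged = converged, singular = singular)
  }

  best <- NULL
  do_starts <- function() {
    inits <- c(list(kmeans_init(dataset, k)),
               replicate(max(n_starts - 1, 1), random_init(),
                         simplify = FALSE))
    inits <- Filter(Negate(is.null), inits)
    attempts <- 0L
    for (init in inits) {
      cand <- run_em(init)
      while (is.null(cand) && attempts < 5L) {
        attempts <- attempts + 1L
        cand <- run_em(random_init())
      }
      if (!is.null(cand) && (is.null(best) || cand$ll > best$ll))
        best <<- cand
    }
    if (is.null(best))
      stop("EM failed from every initialization: weighted design singular")
  }
  if (is.null(seed)) do_starts() else with_preserved_seed(seed, do_starts())

  model <- best$model
  resp <- best$resp
  modal <- max.col(resp)
  share <- tabulate(modal, ncol(resp)) / P
  pruned <- which(share < prune_threshold)
  if (length(pruned) && length(pruned) < model$k) {
    keep <- setdiff(seq_len(model$k), pruned)
    model <- reorder_model(model, keep)
    resp <- e_step(model, dataset)
  }
  ord <- order(model$betas[, "log_age"], decreasing = TRUE)
  model <- reorder_model(model, ord)
  model$pruned <- pruned
  final <- e_step(model, dataset)
  resp <- final
  ll_final <- attr(final, "loglik")

  structure(
    list(model = model, responsibilities = resp,
         trace = list(loglik = best$ll_trace, iterations = length(best$ll_trace),
                      converged = best$converged, seed = seed,
                      final_loglik = ll_final, pruned = pruned)),
    class = "mor_fit")
}

#' @export
print.mor_fit <- function(x, ...) {
  print(x$model)
  cat("log-likelihood:",
      format(x$trace$final_loglik %||% x$trace$loglik[x$trace$iterations]),
      "| iterations:", x$trace$iterations,
      "| converged:", x$trace$converged, "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Choose the number of clusters by held-out prediction accuracy
#'
#' Fits the mixture for `k = 1..k_max` on the training rows and scores
#' mean squared prediction error on held-out rows (known-PEF mode: a PEF's
#' training responsibilities weight the cluster predictions).  Stops at the
#' smallest `k` whose relative improvement over `k - 1` falls below
#' `improvement_tol` -- asymptotic accuracy -- or at which cluster pruning
#' fires, and returns the previous `k` with the full MSE-vs-k table.
#'
#' @param train,heldout `pef_dataset`s; held-out rows are scored with the
#'   training responsibilities of their PEF (unseen PEFs fall back to
#'   Bayes-rule inference).
#' @param k_max largest cluster count to try.
#' @param improvement_tol minimal relative MSE improvement to keep growing k.
#' @param seed integer seed for the EM initializations.
#' @param ... passed to [fit_mixture()].
#' @return List: `k` (chosen), `table` (data.frame k, mse, pruned flag).
#' @export
select_k <- function(train, heldout, k_max = 8, improvement_tol = 0.01,
                     seed = NULL, ...) {
  stopifnot(k_max >= 1)
  mse <- rep(NA_real_, k_max)
  pruned <- logical(k_max)
  chosen <- k_max
  for (k in seq_len(k_max)) {
    fit <- fit_mixture(train, k,
                       seed = if (is.null(seed)) NULL else seed + k, ...)
    pred <- predict_for_task(fit$model, fit$responsibilities, heldout,
                             mode = "known_pef")
    mse[k] <- mean((pred$predicted_db - pred$observed_db)^2)
    pruned[k] <- length(fit$trace$pruned) > 0
    if (pruned[k] && k > 1) { chosen <- k - 1L; break }
    if (k > 1) {
      rel <- (mse[k - 1] - mse[k]) / mse[k - 1]
      if (rel < improvement_tol) { chosen <- k - 1L; break }
    }
  }
  list(k = chosen,
       table = data.frame(k = seq_len(k_max), mse = mse,
                          pruned = pruned)[!is.na(mse), ])
}

#' Serialize / restore a fitted mixture model as JSON
#'
#' @param model a `mor_model`.
#' @param path output (input) JSON path.
#' @return `read_mor_model()` returns the `mor_model`.
#' @export
write_mor_model <- function(model, path) {
  jsonlite::write_json(
    list(k = model$k, betas = model$betas, sigma2s = model$sigma2s,
         mixing = model$mixing, column_names = model$column_names,
         pruned = model$pruned),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_mor_model
#' @export
read_mor_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_mor_model(j$betas, j$sigma2s, j$mixing,
                pruned = as.integer(j$pruned))
}
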