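test_that("per-PEF log-likelihood matches the direct Gaussian density", {
  model <- audmix:::new_mor_model(rbind(c(20, 2, 0, 0), c(40, -1, 3, 1)),
                                  c(1 / (2 * pi), 9), c(0.4, 0.6))
  # a single row sitting exactly on the cluster line with var 1/(2*pi)
  d1 <- toy_dataset(ages = 1, thresholds = 20)
  expect_equal(pef_log_likelihood(model, d1, 1), 0)

  # additivity over rows and agreement with a brute-force product
  d3 <- toy_dataset(ages = c(1, 2, 4), thresholds = c(35, 31, 38),
                    gender_f = 1, diag_count = c(0, 1, 3))
  ll <- pef_log_likelihood(model, d3, 2)
  X <- cbind(1, log(c(1, 2, 4)), 1, log(c(1, 2, 4)))
  direct <- sum(log(dnorm(c(35, 31, 38), drop(X %*% c(40, -1, 3, 1)), 3)))
  expect_equal(ll, direct, tolerance = 1e-12)
  expect_equal(ll, pef_log_likelihood(model, d3[1:2, ], 2) +
                 pef_log_likelihood(model, d3[3, ], 2), tolerance = 1e-12)
  expect_error(pef_log_likelihood(model, d3[0, ], 1), "at least one row")
})

test_that("E-step matches brute-force enumeration and handles symmetry", {
  d <- prepared_cohort(generator_config(n_pefs = 5, seed = 8))
  # identical clusters: posterior must be the prior everywhere
  sym <- audmix:::new_mor_model(rbind(c(30, 1, 0, 0), c(30, 1, 0, 0)),
                                c(25, 25), c(0.5, 0.5))
  r <- e_step(sym, d)
  expect_true(all(abs(r - 0.5) < 1e-12))

  model <- audmix:::new_mor_model(
    rbind(c(55, 3, 1, 0), c(30, 0.5, -2, 1), c(10, -1, 0, 0.5)),
    c(16, 25, 9), c(0.2, 0.5, 0.3))
  r <- e_step(model, d)
  expect_true(all(abs(rowSums(r) - 1) < 1e-10))
  oracle <- estep_oracle(model, d)
  expect_equal(unclass(r)[rownames(oracle), ], oracle, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("E-step assigns a PEF on a well-separated cluster line to that cluster", {
  model <- audmix:::new_mor_model(rbind(c(60, 2, 0, 0), c(10, -1, 0, 0)),
                                  c(25, 25), c(0.5, 0.5))
  d <- toy_dataset(ages = c(1, 2, 3, 5),
                   thresholds = 60 + 2 * log(c(1, 2, 3, 5)))
  r <- e_step(model, d)
  expect_gt(r[1, 1], 0.99)
})

test_that("M-step solves the weighted regressions it claims", {
  cfg <- generator_config(n_pefs = 60, k_true = 2,
                          cluster_betas = rbind(c(50, 2, 3, 0.5),
                                                c(15, -1, 0, 0.2)),
                          cluster_sigmas = c(1e-9, 1e-9), mixing = c(0.5, 0.5),
                          seed = 14)
  co <- generate_cohort(cfg)
  d <- build_design(code_pefs(co$records))
  keys <- unique(d$pef_key)
  z <- co$truth$pef_cluster[keys]
  hard <- cbind(as.numeric(z == 1), as.numeric(z == 2))
  rownames(hard) <- keys
  m <- m_step(d, hard)
  expect_lt(max(abs(m$betas - cfg$cluster_betas)), 1e-6)

  # uniform responsibilities: every cluster equals the pooled OLS fit
  unif <- matrix(0.5, length(keys), 2, dimnames = list(keys, NULL))
  mu <- m_step(d, unif)
  ols <- fit_ols(d)
  expect_equal(unname(mu$betas[1, ]), unname(ols$beta), tolerance = 1e-8)
  expect_equal(unname(mu$betas[2, ]), unname(ols$beta), tolerance = 1e-8)

  # a cluster with no responsibility is a singular weighted design
  dead <- cbind(rep(1, length(keys)), 0)
  rownames(dead) <- keys
  expect_error(m_step(d, dead), "cluster 2")
})

test_that("k = 1 mixture is exactly the pooled OLS fit", {
  d <- prepared_cohort(generator_config(n_pefs = 60, seed = 17))
  fit <- fit_mixture(d, 1)
  ols <- fit_ols(d)
  expect_equal(unname(fit$model$betas[1, ]), unname(ols$beta),
               tolerance = 1e-12)
  expect_equal(fit$model$sigma2s, ols$sigma2, tolerance = 1e-12)
  expect_true(fit$trace$converged)
})

test_that("EM recovers a well-separated three-cluster structure", {
  d <- prepared_cohort(recovery_config(101, n_pefs = 300))
  truth <- attr(d, "truth")
  fit <- fit_mixture(d, 3, seed = 1)
  expect_true(fit$trace$converged)
  # log-likelihood is non-decreasing along the winning trace
  expect_true(all(diff(fit$trace$loglik) >= -1e-8))
  # clusters are reported in descending log-age order
  expect_true(all(diff(fit$model$betas[, "log_age"]) <= 0))
  ari <- mclust::adjustedRandIndex(
    max.col(fit$responsibilities),
    truth$pef_cluster[rownames(fit$responsibilities)])
  expect_gt(ari, 0.95)
  # coefficient error is bounded by sampling noise at this size: the
  # per-cluster OLS information limit puts intercept SEs near 0.5 dB here
  expect_lt(max(abs(fit$model$betas - recovery_betas())), 1.5)
})

test_that("overfitted k prunes clusters below 1% of PEFs", {
  d <- prepared_cohort(recovery_config(7, n_pefs = 150))
  fit <- fit_mixture(d, 8, seed = 2, n_starts = 3)
  expect_gt(length(fit$trace$pruned), 0)
  expect_lt(fit$model$k, 8)
  modal <- max.col(fit$responsibilities)
  expect_true(all(tabulate(modal, fit$model$k) / 150 >= 0.01))
})

test_that("label permutation leaves likelihood and predictions unchanged", {
  d <- prepared_cohort(generator_config(n_pefs = 40, seed = 23))
  fit <- fit_mixture(d, 3, seed = 3, n_starts = 2)
  model <- fit$model
  perm <- c(3, 1, 2)
  permuted <- audmix:::reorder_model(model, perm)
  expect_equal(attr(e_step(model, d), "loglik"),
               attr(e_step(permuted, d), "loglik"), tolerance = 1e-10)
  post <- infer_membership(model, d[1:4, ])
  post_p <- infer_membership(permuted, d[1:4, ])
  expect_equal(post$probs[perm], post_p$probs, tolerance = 1e-10)
  expect_equal(predict_threshold(model, post, d[1:4, ]),
               predict_threshold(permuted, post_p, d[1:4, ]),
               tolerance = 1e-10)
})

test_that("select_k finds one cluster on pooled data and three on clustered data", {
  d1 <- prepared_cohort(generator_config(
    n_pefs = 80, k_true = 1, cluster_betas = matrix(c(30, 1, 0.5, 0.3), 1),
    cluster_sigmas = 5, mixing = 1, seed = 3))
  folds <- make_imputation_folds(d1, seed = 1)
  sel1 <- select_k(d1[folds$bin != 1, ], d1[folds$bin == 1, ], k_max = 3,
                   seed = 5, n_starts = 2)
  expect_equal(sel1$k, 1)

  d3 <- prepared_cohort(recovery_config(19, n_pefs = 200))
  folds3 <- make_imputation_folds(d3, seed = 1)
  sel3 <- select_k(d3[folds3$bin != 1, ], d3[folds3$bin == 1, ], k_max = 5,
                   seed = 5, n_starts = 3)
  expect_equal(sel3$k, 3)
  mse <- sel3$table$mse
  expect_true(all(diff(mse[1:3]) < 0))
})

test_that("fitted models round-trip through JSON", {
  d <- prepared_cohort(generator_config(n_pefs = 40, seed = 29))
  fit <- fit_mixture(d, 2, seed = 4, n_starts = 2)
  path <- tempfile(fileext = ".json")
  write_mor_model(fit$model, path)
  back <- read_mor_model(path)
  expect_equal(back$betas, fit$model$betas, tolerance = 1e-12)
  expect_equal(back$sigma2s, fit$model$sigma2s, tolerance = 1e-12)
  expect_equal(back$mixing, fit$model$mixing, tolerance = 1e-12)
})
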