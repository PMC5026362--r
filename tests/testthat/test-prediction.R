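two_cluster_model <- function(sigma2 = c(25, 25), mixing = c(0.5, 0.5)) {
  audmix:::new_mor_model(rbind(c(60, 2, 0, 0), c(10, -1, 0, 0)),
                         sigma2, mixing)
}

test_that("zero observations give exactly the mixing prior", {
  model <- two_cluster_model(mixing = c(0.3, 0.7))
  d <- toy_dataset(ages = 1, thresholds = 30)
  post <- infer_membership(model, d[0, ])
  expect_identical(post$probs, c(0.3, 0.7))
  expect_identical(post$n_obs_used, 0L)
})

test_that("a 3:1 density ratio gives a (0.75, 0.25) posterior", {
  # one observation; equal priors and variances; the mean offset delta with
  # exp(-delta^2 / (2 sigma^2)) = 1/3 makes the density ratio exactly 3
  sigma2 <- 4
  delta <- sqrt(2 * sigma2 * log(3))
  model <- audmix:::new_mor_model(rbind(c(30, 0, 0, 0),
                                        c(30 + delta, 0, 0, 0)),
                                  c(sigma2, sigma2), c(0.5, 0.5))
  d <- toy_dataset(ages = 1, thresholds = 30)
  post <- infer_membership(model, d)
  expect_equal(post$probs, c(0.75, 0.25), tolerance = 1e-12)
})

test_that("rows from a separated cluster concentrate the posterior on it", {
  model <- two_cluster_model()
  d <- toy_dataset(ages = c(1, 2, 3, 5),
                   thresholds = 10 - 1 * log(c(1, 2, 3, 5)))
  post <- infer_membership(model, d)
  expect_gt(post$probs[2], 0.99)
})

test_that("posterior-weighted prediction is the stated convex combination", {
  model <- audmix:::new_mor_model(rbind(c(10, 0, 0, 0), c(20, 0, 0, 0)),
                                  c(1, 1), c(0.5, 0.5))
  row <- toy_dataset(ages = 1, thresholds = 0)
  expect_equal(predict_threshold(model, c(0.3, 0.7), row), 17)
  expect_equal(predict_threshold(model, c(1, 0), row), 10)
  # identical clusters: prediction ignores the posterior
  same <- audmix:::new_mor_model(rbind(c(15, 1, 0, 0), c(15, 1, 0, 0)),
                                 c(1, 1), c(0.5, 0.5))
  expect_equal(predict_threshold(same, c(0.2, 0.8), row),
               predict_threshold(same, c(0.9, 0.1), row))
  expect_error(predict_threshold(model, c(0.5, 0.3, 0.2), row),
               "does not match k")
})

test_that("predictions stay inside the cluster-prediction envelope", {
  d <- prepared_cohort(recovery_config(61, n_pefs = 80))
  fit <- fit_mixture(d, 3, seed = 6, n_starts = 2)
  pred <- predict_for_task(fit$model, fit$responsibilities, d,
                           mode = "known_pef")
  cluster_preds <- design_matrix(d) %*% t(fit$model$betas)
  expect_true(all(pred$predicted_db >= apply(cluster_preds, 1, min) - 1e-9))
  expect_true(all(pred$predicted_db <= apply(cluster_preds, 1, max) + 1e-9))
})

test_that("known-PEF mode with hard responsibilities equals the assigned cluster line", {
  model <- two_cluster_model()
  d <- toy_dataset(ages = c(1, 2, 3, 5), thresholds = c(1, 2, 3, 4))
  hard <- matrix(c(1, 0), 1, 2, dimnames = list(d$pef_key[1], NULL))
  pred <- predict_for_task(model, hard, d, mode = "known_pef")
  expect_equal(pred$predicted_db, 60 + 2 * d$log_age, tolerance = 1e-12)
  expect_true(all(pred$mode == "known_pef"))
  expect_false(any(pred$fallback))

  # PEF absent from training responsibilities falls through to new-PEF path
  other <- matrix(c(1, 0), 1, 2, dimnames = list("Z:left:500", NULL))
  pred2 <- predict_for_task(model, other, d, mode = "known_pef")
  expect_true(all(pred2$fallback))
  expect_true(all(pred2$mode == "new_pef"))
})

test_that("posterior concentration grows with conditioning observations", {
  model <- two_cluster_model()
  set.seed(71)
  n_pef <- 80
  mass <- matrix(NA_real_, n_pef, 5)    # conditioning sizes 0..4
  for (i in seq_len(n_pef)) {
    ages <- sort(runif(5, 1, 20))
    d <- toy_dataset(ages = ages,
                     thresholds = 60 + 2 * log(ages) + rnorm(5, 0, 5))
    for (n_cond in 0:4)
      mass[i, n_cond + 1] <-
        infer_membership(model, d[seq_len(n_cond), ])$probs[1]
  }
  avg <- colMeans(mass)
  expect_true(all(diff(avg) > -1e-6))
  expect_equal(avg[1], 0.5)
  expect_gt(avg[5], 0.9)
})

test_that("conditioning protocols use the rows they claim", {
  model <- two_cluster_model()
  d <- toy_dataset(ages = c(1, 2, 4, 8),
                   thresholds = 60 + 2 * log(c(1, 2, 4, 8)))
  p_all <- predict_for_task(model, NULL, d, mode = "new_pef",
                            condition = "all")
  expect_true(all(p_all$n_cond == 4))
  p_loo <- predict_for_task(model, NULL, d, mode = "new_pef",
                            condition = "loo")
  expect_true(all(p_loo$n_cond == 3))
  p_pre <- predict_for_task(model, NULL, d, mode = "new_pef",
                            condition = "prefix")
  expect_equal(p_pre$n_cond, 0:3)
  expect_true(p_pre$prior_only[1])
  expect_equal(p_pre$p1[1], 0.5)   # first row predicted from the prior
})

test_that("prediction never mutates the fitted model", {
  d <- prepared_cohort(generator_config(n_pefs = 40, seed = 73))
  fit <- fit_mixture(d, 2, seed = 9, n_starts = 2)
  before <- serialize(fit$model, NULL)
  invisible(predict_for_task(fit$model, fit$responsibilities, d,
                             mode = "known_pef"))
  invisible(predict_for_task(fit$model, NULL, d, mode = "new_pef"))
  invisible(infer_membership(fit$model, d[1:3, ]))
  expect_identical(serialize(fit$model, NULL), before)
})
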