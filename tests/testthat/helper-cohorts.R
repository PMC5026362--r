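# Shared cohort configurations and small oracles used across test files.
# All fixtures are generated in code; nothing is read from disk.

# well-separated three-cluster recovery conditions: 500 PEFs x 6 tests,
# sigma 5 dB, intercepts >= 20 dB apart, small gender/diagnosis effects so
# the cluster lines never cross inside the age range
recovery_betas <- function() {
  rbind(c(60, 3, 2, 0.4),
        c(35, 1, -2, 0.5),
        c(12, -1.5, 0, 0.2))
}

recovery_config <- function(seed, n_pefs = 500) {
  generator_config(n_pefs = n_pefs, tests_per_pef = c(6L, 6L),
                   cluster_betas = recovery_betas(),
                   cluster_sigmas = rep(5, 3), seed = seed)
}

# single-cluster cohort with large PEF-level random effects (between-
# individual variation dominates): intercept SD 10 dB, log-age slope SD 1.5
random_effects_config <- function(seed, n_pefs = 150) {
  generator_config(n_pefs = n_pefs, k_true = 1,
                   cluster_betas = matrix(c(30, 1, 0.5, 0.3), 1),
                   cluster_sigmas = 5, mixing = 1,
                   random_effect_sd = c(10, 1.5, 0, 0), seed = seed)
}

# drift cohort: cluster structure + random intercepts + 5 dB/yr drift of
# the final observation's mean, at the cohort scale of the study design
# (order 10^3 PEF series)
drift_config <- function(seed, n_pefs = 800) {
  generator_config(n_pefs = n_pefs, random_effect_sd = c(10, 0, 0, 0),
                   drift_rate = 5, seed = seed)
}

prepared_cohort <- function(config, drift = FALSE) {
  co <- if (drift) generate_drift_cohort(config) else generate_cohort(config)
  d <- prepare_cohort(co$records)
  attr(d, "truth") <- co$truth
  d
}

# independent E-step oracle: per-PEF normalized product of Gaussian
# densities times the mixing prior, computed by direct enumeration
estep_oracle <- function(model, dataset) {
  keys <- unique(dataset$pef_key)
  out <- matrix(NA_real_, length(keys), model$k,
                dimnames = list(keys, NULL))
  for (key in keys) {
    rows <- dataset[dataset$pef_key == key, , drop = FALSE]
    X <- cbind(1, rows$log_age, rows$gender_f, rows$log_diag)
    num <- numeric(model$k)
    for (kk in seq_len(model$k)) {
      dens <- prod(dnorm(rows$threshold_db, drop(X %*% model$betas[kk, ]),
                         sqrt(model$sigma2s[kk])))
      num[kk] <- model$mixing[kk] * dens
    }
    out[key, ] <- num / sum(num)
  }
  out
}

# tiny hand-built dataset: n rows, one or more PEFs, valid design columns
toy_dataset <- function(ages, thresholds, pef = "A:left:500",
                        gender_f = 0, diag_count = 0) {
  d <- data.frame(
    patient_id = sub(":.*", "", pef), ear = "left", conduction = "bone",
    frequency_hz = 500, age_years = ages, gender = ifelse(gender_f == 1, "F", "M"),
    diag_count = diag_count, threshold_db = thresholds,
    pef_key = pef, stringsAsFactors = FALSE)
  d <- build_design(d)
  class(d) <- c("pef_dataset", "data.frame")
  d
}
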