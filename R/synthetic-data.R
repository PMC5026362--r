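# Synthetic audiogram cohort generator: K-cluster mixture of linear
# regressions on [1, log(age), gender, log(diagnoses + 1)] with one latent
# cluster per patient-ear-frequency (PEF) series, optional PEF-level random
# effects, optional within-individual drift of the final observation, and
# optional records violating the inclusion criteria.

#' Configuration for the synthetic audiogram cohort generator
#'
#' Defines the generating conditions of a simulated cohort: number of
#' patient-ear-frequency (PEF) series, tests per series, the latent-cluster
#' regression parameters, and the optional random-effect, drift, and
#' contamination components.
#'
#' The default three clusters sit at paper-scale magnitudes for a pediatric
#' hearing-loss cohort: a severe progressive-loss cluster, a moderate cluster,
#' and a mild cluster whose thresholds improve with age (intercepts 60/35/12
#' dB, log-age slopes 3/1/-1.5 dB).
#'
#' @param n_pefs number of PEF series to generate.
#' @param tests_per_pef integer range `c(min, max)` of tests per PEF;
#'   `min >= 4`, `max <= 21`.  Counts are drawn as `min + Poisson(2)`
#'   truncated at `max` (mean about 6 when the range is 4--21).
#' @param age_range numeric range of ages (years) within `[0, 21]`; tests of
#'   a PEF are sorted uniform draws in this range.
#' @param k_true number of generating clusters.
#' @param cluster_betas `k_true x 4` matrix of coefficients per cluster, in
#'   dB, for columns (intercept, log-age, gender-F, log-diagnoses).
#' @param cluster_sigmas per-cluster residual SD in dB, all `> 0`.
#' @param mixing probability vector of length `k_true`, summing to 1.
#' @param random_effect_sd per-coefficient SD of PEF-level Gaussian
#'   deviations from the cluster coefficients (length 1 or 4; 0 disables).
#' @param drift_rate dB per year of forecast horizon added to the noiseless
#'   mean of each PEF's final observation (0 disables; used by
#'   [generate_drift_cohort()]).
#' @param contamination_rate fraction of output records violating one
#'   inclusion criterion each, in `[0, 1)` (see [inject_contamination()]).
#' @param seed integer seed; identical `(config, seed)` gives byte-identical
#'   output.
#' @return An object of class `generator_config` (a validated list).
#' @export
generator_config <- function(n_pefs = 1000,
                             tests_per_pef = c(4L, 21L),
                             age_range = c(0.5, 21),
                             k_true = 3,
                             cluster_betas = NULL,
                             cluster_sigmas = rep(5, k_true),
                             mixing = rep(1 / k_true, k_true),
                             random_effect_sd = 0,
                             drift_rate = 0,
                             contamination_rate = 0,
                             seed = 1L) {
  if (is.null(cluster_betas)) {
    if (k_true == 3) {
      cluster_betas <- rbind(
        c(60,  3.0, -18, 0.4),
        c(35,  1.0,   8, 0.5),
        c(12, -1.5,   0, 0.2)
      )
    } else {
      stop("cluster_betas must be supplied when k_true != 3")
    }
  }
  cluster_betas <- as.matrix(cluster_betas)
  colnames(cluster_betas) <- design_columns()
  if (nrow(cluster_betas) != k_true)
    stop("k_true (", k_true, ") does not match nrow(cluster_betas) (",
         nrow(cluster_betas), ")")
  if (ncol(cluster_betas) != 4L)
    stop("cluster_betas must have 4 columns")
  if (length(cluster_sigmas) != k_true || any(cluster_sigmas <= 0))
    stop("cluster_sigmas must be ", k_true, " positive values")
  if (length(mixing) != k_true)
    stop("mixing must have length k_true")
  if (abs(sum(mixing) - 1) > 1e-12)
    stop("mixing must sum to 1 (got ", format(sum(mixing), digits = 15), ")")
  if (length(tests_per_pef) != 2L || tests_per_pef[1] < 4 ||
      tests_per_pef[2] > 21 || tests_per_pef[1] > tests_per_pef[2])
    stop("tests_per_pef must be a range within [4, 21]")
  if (length(age_range) != 2L || age_range[1] < 0 || age_range[2] > 21 ||
      age_range[1] >= age_range[2])
    stop("age_range must be an increasing range within [0, 21]")
  if (age_range[1] <= 0)
    stop("age_range minimum must be > 0 (log-age design)")
  if (length(random_effect_sd) == 1L)
    random_effect_sd <- rep(random_effect_sd, 4L)
  if (length(random_effect_sd) != 4L || any(random_effect_sd < 0))
    stop("random_effect_sd must be 1 or 4 non-negative values")
  if (drift_rate < 0) stop("drift_rate must be >= 0")
  if (contamination_rate < 0 || contamination_rate >= 1)
    stop("contamination_rate must be in [0, 1)")
  structure(
    list(n_pefs = as.integer(n_pefs),
         tests_per_pef = as.integer(tests_per_pef),
         age_range = age_range,
         k_true = as.integer(k_true),
         cluster_betas = cluster_betas,
         cluster_sigmas = cluster_sigmas,
         mixing = mixing,
         random_effect_sd = random_effect_sd,
         drift_rate = drift_rate,
         contamination_rate = contamination_rate,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

# Run code under a seed without disturbing the caller's RNG stream.
with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Generate a synthetic audiogram cohort with known ground truth
#'
#' Draws `n_pefs` patient-ear-frequency series.  Each PEF is assigned one
#' latent cluster from `mixing`; all its thresholds follow that cluster's
#' linear regression on (intercept, log-age, gender, log-diagnoses) plus an
#' optional PEF-level random deviation and per-cluster Gaussian noise.  Ages
#' are sorted uniform draws (strictly increasing within a PEF), gender is
#' Bernoulli(0.5) per patient and shared across a patient's PEFs, and the
#' cumulative diagnosis count follows a non-decreasing Poisson-increment
#' path from 0.
#'
#' @param config a [generator_config()].
#' @param drift internal flag: add `drift_rate * gap` to the final
#'   observation's noiseless mean (use [generate_drift_cohort()]).
#' @return A list with elements `records` (data.frame with columns
#'   patient_id, ear, conduction, frequency_hz, age_years, gender,
#'   diag_count, threshold_db) and `truth` (list: `pef_cluster` named
#'   integer vector, `pef_random_effects` matrix, `cluster_betas`,
#'   `cluster_sigmas`, `mixing`, and `drift_added` per PEF).
#' @export
generate_cohort <- function(config, drift = FALSE) {
  stopifnot(inherits(config, "generator_config"))
  if (drift && config$drift_rate <= 0)
    stop("drift cohort requires drift_rate > 0")
  with_preserved_seed(config$seed, {
    n_pefs <- config$n_pefs
    # patients own 1-4 PEFs drawn from the 2-ear x 4-frequency grid
    grid <- expand.grid(ear = c("left", "right"),
                        frequency_hz = c(500, 1000, 2000, 4000),
                        stringsAsFactors = FALSE)
    pef_rows <- list()
    truth_cluster <- integer(n_pefs)
    ranef_mat <- matrix(0, n_pefs, 4L,
                        dimnames = list(NULL, design_columns()))
    drift_added <- numeric(n_pefs)
    keys <- character(n_pefs)

    made <- 0L
    patient <- 0L
    while (made < n_pefs) {
      patient <- patient + 1L
      pid <- sprintf("P%05d", patient)
      gender <- sample(c("M", "F"), 1L)
      n_here <- min(sample(1:4, 1L), n_pefs - made)
      combos <- grid[sample(nrow(grid), n_here), , drop = FALSE]
      for (j in seq_len(n_here)) {
        made <- made + 1L
        z <- sample.int(config$k_true, 1L, prob = config$mixing)
        truth_cluster[made] <- z
        b <- rnorm(4L, 0, config$random_effect_sd)
        ranef_mat[made, ] <- b
        n_tests <- min(config$tests_per_pef[1] + rpois(1L, 2),
                       config$tests_per_pef[2])
        ages <- sort(runif(n_tests, config$age_range[1], config$age_range[2]))
        diag_count <- cumsum(rpois(n_tests, 0.5))
        X <- cbind(1, log(ages), as.numeric(gender == "F"),
                   log(diag_count + 1))
        mu <- drop(X %*% (config$cluster_betas[z, ] + b))
        if (drift) {
          gap <- ages[n_tests] - ages[n_tests - 1L]
          drift_added[made] <- config$drift_rate * gap
          mu[n_tests] <- mu[n_tests] + drift_added[made]
        }
        y <- mu + rnorm(n_tests, 0, config$cluster_sigmas[z])
        keys[made] <- paste(pid, combos$ear[j], combos$frequency_hz[j],
                            sep = ":")
        pef_rows[[made]] <- data.frame(
          patient_id = pid,
          ear = combos$ear[j],
          conduction = "bone",
          frequency_hz = combos$frequency_hz[j],
          age_years = ages,
          gender = gender,
          diag_count = diag_count,
          threshold_db = y,
          stringsAsFactors = FALSE
        )
      }
    }
    records <- do.call(rbind, pef_rows)
    rownames(records) <- NULL
    names(truth_cluster) <- keys
    rownames(ranef_mat) <- keys
    names(drift_added) <- keys
    list(records = records,
         truth = list(pef_cluster = truth_cluster,
                      pef_random_effects = ranef_mat,
                      cluster_betas = config$cluster_betas,
                      cluster_sigmas = config$cluster_sigmas,
                      mixing = config$mixing,
                      drift_added = drift_added))
  })
}

#' Generate a cohort with within-individual drift at the forecast horizon
#'
#' As [generate_cohort()], but the final observation of every PEF has
#' `drift_rate * (years since the previous test)` added to its noiseless
#' mean.  Models fitted to the earlier observations therefore face a future
#' observation whose mean has moved, and their forecast error grows with
#' the time gap.
#'
#' @inheritParams generate_cohort
#' @return As [generate_cohort()]; `truth$drift_added` records the dB shift
#'   applied to each PEF's last observation.
#' @export
generate_drift_cohort <- function(config) {
  generate_cohort(config, drift = TRUE)
}

#' Append records that violate the inclusion criteria
#'
#' Adds records that each violate exactly one criterion of the filtering
#' stage -- an air-conduction test, an off-grid frequency, a zero threshold,
#' an age above 21, or a PEF with fewer than 4 tests -- so that filter tests
#' can count removals per criterion.  Injected records carry their violated
#' criterion in a `bad_criterion` column (`NA` for clean records); the
#' number injected makes bad records a `contamination_rate` fraction of the
#' output.
#'
#' @param records a cohort record table ([generate_cohort()]).
#' @param config the [generator_config()] (uses `contamination_rate` and
#'   `seed`).
#' @return The record table; unchanged if `contamination_rate` is 0,
#'   otherwise with appended tagged records and the `bad_criterion` column.
#' @export
inject_contamination <- function(records, config) {
  stopifnot(inherits(config, "generator_config"))
  rate <- config$contamination_rate
  if (rate == 0) return(records)
  with_preserved_seed(config$seed + 7919L, {
    n <- nrow(records)
    n_bad <- max(1L, round(rate / (1 - rate) * n))
    types <- rep(c("conduction", "frequency", "zero_threshold",
                   "age_range", "min_tests"), length.out = n_bad)
    template <- records[sample(n, n_bad, replace = TRUE), , drop = FALSE]
    bad <- template
    bad$bad_criterion <- types
    for (i in seq_len(n_bad)) {
      switch(types[i],
        conduction = { bad$conduction[i] <- "air" },
        frequency = { bad$frequency_hz[i] <- 3000 },
        zero_threshold = { bad$threshold_db[i] <- 0 },
        age_range = { bad$age_years[i] <- runif(1, 21.5, 30) },
        min_tests = {
          # a fresh patient with a single otherwise-valid test
          bad$patient_id[i] <- sprintf("BAD%05d", i)
        })
    }
    records$bad_criterion <- NA_character_
    out <- rbind(records, bad)
    rownames(out) <- NULL
    out
  })
}

#' Write / read a cohort as CSV
#'
#' `write_cohort()` writes `records.csv` and a companion
#' `ground_truth.csv` (`pef_key, true_cluster`) under `dir`;
#' `read_cohort()` reads a record CSV back.
#'
#' @param cohort a list as returned by [generate_cohort()].
#' @param dir output directory (created if missing).
#' @return `write_cohort()` returns the paths invisibly; `read_cohort()`
#'   the record data.frame.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rec_path <- file.path(dir, "records.csv")
  truth_path <- file.path(dir, "ground_truth.csv")
  utils::write.csv(cohort$records, rec_path, row.names = FALSE)
  utils::write.csv(
    data.frame(pef_key = names(cohort$truth$pef_cluster),
               true_cluster = unname(cohort$truth$pef_cluster)),
    truth_path, row.names = FALSE)
  invisible(c(records = rec_path, ground_truth = truth_path))
}

#' @rdname write_cohort
#' @param path path to a records CSV.
#' @export
read_cohort <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
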