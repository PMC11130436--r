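# Synthetic cohort- and worker-level data with the statistical structure the
# analysis assumes, so every pipeline stage is testable without the original
# study records.

# independent deterministic seed per variable, so adding one simulated
# variable does not perturb the draws of the others
substream_seed <- function(seed, name) {
  codes <- utf8ToInt(name)
  h <- sum(codes * seq_along(codes)) %% 32749L
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629)
}

#' Configuration for the synthetic worker generator
#'
#' Defaults emulate the monitored factory population: four
#' cumulative-exposure groups of 23/24/26/25 workers with the observed group
#' means and standard deviations of airborne benzene (2.31+/-0.97,
#' 4.28+/-2.05, 5.31+/-5.84 and 34.92+/-60.37 mg/m^3) and mean working
#' durations (0.76, 1.67, 2.41, 2.70 years); 23.5% smokers; per-worker
#' monitoring of 2-3 rounds; metabolites generated from the published ln-ln
#' regressions with residual noise calibrated so the refitted R^2 matches
#' the published 0.58 (S-PMA) and 0.45 (t,t-MA); and 5 additional workers
#' whose measured air falls below the 0.05 mg/m^3 limit of detection but
#' whose metabolites reflect a true low-level exposure of about
#' 0.01 mg/m^3.
#'
#' @param seed Integer seed; the same configuration always yields the same
#'   dataset.
#' @param n_per_group Workers per exposure group.
#' @param air_mean,air_sd Arithmetic group means and SDs of airborne benzene
#'   (mg/m^3); a log-normal is moment-matched to these.
#' @param duration_mean Group mean working durations, years.
#' @param duration_cv Coefficient of variation of the log-normal working
#'   durations (default 0.5; within-group spread is not pinned down by the
#'   published summaries).
#' @param smoking_prev Smoking prevalence (default 0.235).
#' @param rounds_prob Probabilities of a worker contributing 2 or 3
#'   monitoring rounds (default c(0.79, 0.21), giving ~2.2 samples/worker).
#' @param within_worker_cv CV of the round-to-round variation around a
#'   worker's underlying mean concentration (default 0.3).
#' @param spma_truth,ttma_truth Lists with \code{slope}, \code{smoking},
#'   \code{intercept} and \code{r_squared} used to generate metabolites;
#'   defaults are the published coefficient sets.
#' @param creatinine_range Valid creatinine band, g/L.
#' @param creatinine_outlier_rate Fraction of samples drawn outside the
#'   valid band (default 0.02).
#' @param n_below_lod Number of extra below-LOD workers (default 5).
#' @param below_lod_air True airborne concentration generating the below-LOD
#'   workers' metabolites, mg/m^3 (default 0.01).
#' @param lod Limit of detection, mg/m^3.
#' @return A list of class \code{"synthetic_config"}.
#' @seealso [generate_workers()]
#' @export
synthetic_config <- function(seed = 1L,
                             n_per_group = c(23L, 24L, 26L, 25L),
                             air_mean = c(2.31, 4.28, 5.31, 34.92),
                             air_sd = c(0.97, 2.05, 5.84, 60.37),
                             duration_mean = c(0.76, 1.67, 2.41, 2.70),
                             duration_cv = 0.5,
                             smoking_prev = 0.235,
                             rounds_prob = c(0.79, 0.21),
                             within_worker_cv = 0.3,
                             spma_truth = NULL,
                             ttma_truth = NULL,
                             creatinine_range = c(0.3, 3),
                             creatinine_outlier_rate = 0.02,
                             n_below_lod = 5L,
                             below_lod_air = 0.01,
                             lod = 0.05) {
  as_truth <- function(x, default) {
    if (is.null(x)) x <- unclass(default)[c("slope", "smoking", "intercept",
                                            "r_squared")]
    stopifnot(all(c("slope", "smoking", "intercept", "r_squared") %in%
                    names(x)))
    if (x$r_squared <= 0 || x$r_squared > 1)
      stop("target r_squared must be in (0, 1]", call. = FALSE)
    x
  }
  k <- length(n_per_group)
  stopifnot(length(air_mean) == k, length(air_sd) == k,
            length(duration_mean) == k,
            all(air_sd >= 0), all(air_mean > 0), all(duration_mean > 0),
            smoking_prev >= 0, smoking_prev <= 1,
            creatinine_outlier_rate >= 0, creatinine_outlier_rate <= 1,
            abs(sum(rounds_prob) - 1) < 1e-9)
  structure(list(
    seed = as.integer(seed), n_per_group = as.integer(n_per_group),
    air_mean = air_mean, air_sd = air_sd, duration_mean = duration_mean,
    duration_cv = duration_cv, smoking_prev = smoking_prev,
    rounds_prob = rounds_prob, within_worker_cv = within_worker_cv,
    spma_truth = as_truth(spma_truth, metabolite_coefs("spma")),
    ttma_truth = as_truth(ttma_truth, metabolite_coefs("ttma")),
    creatinine_range = creatinine_range,
    creatinine_outlier_rate = creatinine_outlier_rate,
    n_below_lod = as.integer(n_below_lod), below_lod_air = below_lod_air,
    lod = lod
  ), class = "synthetic_config")
}

# log-normal moment-matched to an arithmetic mean m and SD s
rlnorm_moments <- function(n, m, s) {
  if (s == 0) return(rep(m, n))
  sdlog2 <- log(1 + (s / m)^2)
  stats::rlnorm(n, meanlog = log(m) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' Simulate grouped cohort incidence data from a known multistage model
#'
#' Case counts are drawn as Binomial(n_subjects, P(dose)) under the given
#' model, enabling parameter-recovery experiments for [fit_multistage()].
#'
#' @param truth A \code{"multistage"} model generating the data.
#' @param dose_midpoint Group dose midpoints, mg/m^3-year.
#' @param n_subjects Group sizes.
#' @param seed Optional integer seed.
#' @return A [dose_groups()] table (groups with zero subjects are dropped,
#'   contributing zero cases by construction).
#' @examples
#' generate_cohort(benzene_cohort_lms(), c(0, 65, 388),
#'                 c(35804, 31923, 24605), seed = 1)
#' @export
generate_cohort <- function(truth, dose_midpoint, n_subjects, seed = NULL) {
  stopifnot(inherits(truth, "multistage"),
            length(dose_midpoint) == length(n_subjects))
  if (!is.null(seed)) set.seed(seed)
  p <- multistage_probability(truth, dose_midpoint)
  cases <- ifelse(n_subjects > 0,
                  stats::rbinom(length(p), n_subjects, p), 0)
  keep <- n_subjects > 0
  dose_groups(dose_midpoint[keep], n_subjects[keep], cases[keep])
}

#' Simulate per-worker benzene exposure records
#'
#' Generates a worker table and a per-round sample table with the structure
#' the pipeline expects. Per worker: an underlying mean airborne
#' concentration drawn from a log-normal moment-matched to the group's
#' arithmetic mean and SD; 2-3 monitoring rounds whose measured air varies
#' around that mean with a log-normal multiplicative error; a log-normal
#' working duration; and a Bernoulli smoking status. Per round: ln S-PMA and
#' ln t,t-MA follow the configured ln-ln regressions of the round's true air
#' concentration plus Gaussian residual noise whose SD is calibrated to the
#' target R^2 via \eqn{\sigma^2 = b^2\,\mathrm{Var}(\ln C)(1 - R^2)/R^2};
#' creatinine is uniform in the valid band except for a configured outlier
#' fraction. Below-LOD workers are appended with the measured air set to the
#' true low concentration and metabolites generated from it; they are
#' non-smokers.
#'
#' Each random variable uses its own deterministic substream of \code{seed},
#' so the same configuration reproduces the dataset exactly.
#'
#' @param config A [synthetic_config()].
#' @return List with \code{workers} (worker_id, group, smoker,
#'   duration_years, below_lod) and \code{samples} (worker_id, sample_round,
#'   air_benzene_mg_m3, spma_ug_gcr, ttma_ug_gcr, creatinine_g_l, smoker).
#'   The calibrated residual SDs are attached as attribute
#'   \code{"residual_sd"}.
#' @examples
#' sim <- generate_workers(synthetic_config(seed = 7))
#' head(sim$samples)
#' @export
generate_workers <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  k <- length(config$n_per_group)
  n_exp <- sum(config$n_per_group)
  n_all <- n_exp + config$n_below_lod
  grp <- rep(seq_len(k), config$n_per_group)
  id <- sprintf("W%03d", seq_len(n_all))
  below <- c(rep(FALSE, n_exp), rep(TRUE, config$n_below_lod))

  with_seed <- function(name, expr) {
    set.seed(substream_seed(config$seed, name))
    expr
  }

  duration <- with_seed("duration", {
    m <- c(config$duration_mean[grp],
           rep(config$duration_mean[1], config$n_below_lod))
    rlnorm_moments(n_all, 1, config$duration_cv) * m
  })
  smoker <- with_seed("smoking",
    as.integer(stats::runif(n_all) < config$smoking_prev))
  smoker[below] <- 0L
  worker_mean <- with_seed("air_worker", {
    wm <- numeric(n_exp)
    for (g in seq_len(k))
      wm[grp == g] <- rlnorm_moments(sum(grp == g), config$air_mean[g],
                                     config$air_sd[g])
    c(wm, rep(config$below_lod_air, config$n_below_lod))
  })
  rounds <- with_seed("rounds",
    sample(c(2L, 3L), n_all, replace = TRUE, prob = config$rounds_prob))

  widx <- rep(seq_len(n_all), rounds)
  round_no <- sequence(rounds)
  n_samp <- length(widx)
  cv <- config$within_worker_cv
  air_true <- with_seed("air_round",
    worker_mean[widx] * rlnorm_moments(n_samp, 1, cv))
  # below-LOD workers: the monitor reads below the detection limit; record
  # the true low value (it is < LOD by construction)
  air_meas <- air_true
  air_meas[below[widx]] <- pmin(air_meas[below[widx]], 0.9 * config$lod)

  ln_air <- log(air_true)
  v <- stats::var(ln_air[!below[widx]])
  met <- function(truth, name) {
    sdres <- abs(truth$slope) *
      sqrt(v * (1 - truth$r_squared) / truth$r_squared)
    mu <- truth$slope * ln_air + truth$smoking * smoker[widx] +
      truth$intercept
    list(value = with_seed(name, exp(mu + stats::rnorm(n_samp, 0, sdres))),
         sd = sdres)
  }
  spma <- met(config$spma_truth, "spma")
  ttma <- met(config$ttma_truth, "ttma")

  creat <- with_seed("creatinine", {
    lo <- config$creatinine_range[1]; hi <- config$creatinine_range[2]
    cc <- stats::runif(n_samp, lo, hi)
    out <- stats::runif(n_samp) < config$creatinine_outlier_rate
    n_out <- sum(out)
    if (n_out) {
      high <- stats::runif(n_out) < 0.5
      cc[out] <- ifelse(high, stats::runif(n_out, hi + 0.01, hi + 1),
                        stats::runif(n_out, 0.05, lo - 0.01))
    }
    cc
  })

  group_labels <- if (k == 4) c("<3", "3-5", "5-12", ">=12") else
    paste0("G", seq_len(k))
  workers <- data.frame(
    worker_id = id,
    group = c(group_labels[grp], rep(NA_character_, config$n_below_lod)),
    smoker = smoker,
    duration_years = duration,
    below_lod = below
  )
  samples <- data.frame(
    worker_id = id[widx],
    sample_round = round_no,
    air_benzene_mg_m3 = air_meas,
    spma_ug_gcr = spma$value,
    ttma_ug_gcr = ttma$value,
    creatinine_g_l = creat,
    smoker = smoker[widx]
  )
  structure(list(workers = workers, samples = samples),
            residual_sd = c(spma = spma$sd, ttma = ttma$sd))
}
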