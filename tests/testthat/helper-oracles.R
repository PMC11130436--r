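# Brute-force grid oracle for the degree-1 multistage likelihood,
# independent of the package's optimizer.
grid_best_loglik <- function(groups, r_range, a_range, k = 50) {
  d <- groups$dose_midpoint; n <- groups$n_subjects; x <- groups$n_cases
  rs <- seq(r_range[1], r_range[2], length.out = k)
  as <- seq(a_range[1], a_range[2], length.out = k)
  best <- -Inf
  for (r in rs) {
    for (a in as) {
      p <- r + (1 - r) * (1 - exp(-a * d))
      ll <- sum(dbinom(x, n, p, log = TRUE))
      if (ll > best) best <- ll
    }
  }
  best
}

# direct transcription of the dose-response formula, kept separate from the
# package implementation
lms_formula <- function(r, a1, d) r + (1 - r) * (1 - exp(-a1 * d))
lms_formula_poly <- function(r, a, d)
  r + (1 - r) * (1 - exp(-sapply(d, function(di)
    sum(a * di^seq_along(a)))))

# random small degree-1 cohort for oracle comparisons
random_small_cohort <- function() {
  r <- runif(1, 0.005, 0.05)
  a <- 10^runif(1, -4, -2.5)
  d <- c(0, sort(runif(2, 20, 400)))
  n <- sample(200:2000, 3, replace = TRUE)
  p <- lms_formula(r, a, d)
  dose_groups(d, n, rbinom(3, n, p))
}

# noise-free samples generated exactly from a coefficient set, for
# deterministic regression recovery
exact_loglog_samples <- function(coefs, n = 40) {
  air <- exp(seq(log(0.2), log(40), length.out = n))
  smo <- rep(c(0L, 1L), length.out = n)
  data.frame(
    worker_id = sprintf("W%03d", seq_len(n)),
    air_benzene_mg_m3 = air,
    spma_ug_gcr = exp(0.77 * log(air) + 0.12 * smo + 0.54),
    ttma_ug_gcr = exp(coefs$slope * log(air) + coefs$smoking * smo +
                        coefs$intercept),
    creatinine_g_l = 1,
    smoker = smo
  )
}
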