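test_that("generation is deterministic given a configuration", {
  cfg <- synthetic_config(seed = 9)
  s1 <- generate_workers(cfg)
  s2 <- generate_workers(cfg)
  expect_identical(s1, s2)
  s3 <- generate_workers(synthetic_config(seed = 10))
  expect_false(identical(s1$samples, s3$samples))
  g1 <- generate_cohort(benzene_cohort_lms(), c(0, 65, 388),
                        c(1000, 1000, 1000), seed = 4)
  g2 <- generate_cohort(benzene_cohort_lms(), c(0, 65, 388),
                        c(1000, 1000, 1000), seed = 4)
  expect_identical(g1, g2)
})

test_that("generated structure matches the study design", {
  sim <- generate_workers(synthetic_config(seed = 2))
  expect_equal(nrow(sim$workers), 103L)
  expect_equal(sum(sim$workers$below_lod), 5L)
  rounds <- table(sim$samples$worker_id)
  expect_true(all(rounds %in% 2:3))
  expect_true(all(sim$samples$spma_ug_gcr > 0 & sim$samples$ttma_ug_gcr > 0))
  # below-LOD workers: measured air under the detection limit, non-smokers
  bl <- sim$workers$worker_id[sim$workers$below_lod]
  expect_true(all(sim$samples$air_benzene_mg_m3[
    sim$samples$worker_id %in% bl] < 0.05))
  expect_true(all(sim$workers$smoker[sim$workers$below_lod] == 0))
})

test_that("cohort simulation respects degenerate inputs", {
  truth <- benzene_cohort_lms()
  g <- generate_cohort(truth, c(0, 100, 1000, 2000), c(500, 500, 0, 500),
                       seed = 8)
  expect_equal(nrow(g), 3L)  # the empty stratum contributes nothing
  expect_true(all(g$n_cases <= g$n_subjects))
  # zero slope: response probability identical at every dose
  flat <- structure(list(r = 0.05, a = c(a1 = 0), degree = 1L,
                         loglik = NA_real_, converged = TRUE, groups = NULL,
                         df.residual = NA_integer_), class = "multistage")
  expect_equal(multistage_probability(flat, c(0, 10, 1e4)), rep(0.05, 3))
})

test_that("group air-benzene means match their targets at large n", {
  cfg <- synthetic_config(seed = 5, n_per_group = rep(10000L, 4),
                          n_below_lod = 0L)
  sim <- generate_workers(cfg)
  per_worker <- tapply(sim$samples$air_benzene_mg_m3,
                       sim$samples$worker_id, mean)
  grp <- sim$workers$group[match(names(per_worker), sim$workers$worker_id)]
  means <- tapply(per_worker, grp, mean)[c("<3", "3-5", "5-12", ">=12")]
  expect_lt(max(abs(as.numeric(means) / c(2.31, 4.28, 5.31, 34.92) - 1)),
            0.05)
})

test_that("regression refits recover the generating coefficients", {
  sim <- generate_workers(synthetic_config(seed = 6))
  qc <- qc_filter(sim$samples)
  fit <- fit_loglog_regression(qc$valid, "spma")
  ci <- confint(fit$model)["ln_air", ]
  expect_true(ci[1] <= 0.77 && 0.77 <= ci[2])
  expect_equal(fit$r_squared, 0.58, tolerance = 0.12)
  # zero residual noise reproduces the coefficients exactly
  exact <- generate_workers(synthetic_config(
    seed = 6, ttma_truth = list(slope = 0.68, smoking = 0.08,
                                intercept = 4.73, r_squared = 1)))
  qc2 <- qc_filter(exact$samples)
  # summary.lm warns about the (intended) perfect fit
  fit2 <- suppressWarnings(fit_loglog_regression(qc2$valid, "ttma"))
  expect_equal(fit2$slope, 0.68, tolerance = 1e-9)
  expect_equal(fit2$r_squared, 1, tolerance = 1e-9)
})

test_that("infeasible targets and downstream rank errors are surfaced", {
  expect_error(synthetic_config(ttma_truth = list(
    slope = 0.68, smoking = 0.08, intercept = 4.73, r_squared = 1.2)),
    "r_squared")
  sim <- generate_workers(synthetic_config(seed = 13, smoking_prev = 0))
  qc <- qc_filter(sim$samples)
  expect_error(fit_loglog_regression(qc$valid, "spma"), "rank-deficient")
})

test_that("synthetic pipeline closes the loop with the dose-response model", {
  fit <- benzene_cohort_lms()
  sim <- generate_workers(synthetic_config(seed = 12))
  qc <- qc_filter(sim$samples)
  expo <- assign_groups(aggregate_workers(qc$valid, sim$workers))
  s <- group_risk_summary(expo, fit)
  s <- s[s$n >= 2, ]
  # group mean of per-worker risks agrees with the risk at the group's mean
  # cumulative exposure (near-linearity at these doses)
  expect_lt(max(abs(s$risk / multistage_probability(fit, s$mean_ce) - 1)),
            0.02)
})
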