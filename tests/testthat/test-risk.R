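test_that("only the product C_TWA x T matters", {
  fit <- benzene_cohort_lms()
  cc <- c(0.5, 2.31, 34.92); tt <- c(0.76, 1.78, 45)
  for (c1 in cc) for (t1 in tt)
    expect_identical(risk_from_twa(fit, c1, t1),
                     risk_from_twa(fit, c1 * t1, 1))
  expect_identical(risk_from_twa(fit, 0, 10), fit$r)
  expect_error(risk_from_twa(fit, -1, 1), "c_twa")
  expect_error(risk_from_twa(fit, 1, -1), "t must")
})

test_that("risk evaluation matches independent closed-form arithmetic", {
  fit <- benzene_cohort_lms()
  # 45 years at the low-group mean concentration
  expect_equal(risk_from_twa(fit, 2.31, 45),
               lms_formula(4.32e-4, 1.38e-6, 2.31 * 45))
  expect_equal(round(1e4 * risk_from_twa(fit, 1.62, 1), 2), 4.34)
})

test_that("added and extra risk decompose the response", {
  fit <- benzene_cohort_lms()
  z <- excess_and_extra_risk(fit, 0)
  expect_equal(z$added, 0)
  expect_equal(z$extra, 0)
  e <- excess_and_extra_risk(fit, 86.79)
  expect_equal(e$added, lms_formula(4.32e-4, 1.38e-6, 86.79) - 4.32e-4)
  expect_equal(e$extra, e$added / (1 - 4.32e-4))
  # no background: added and extra coincide
  f0 <- structure(list(r = 0, a = c(a1 = 1e-4), degree = 1L,
                       loglik = NA_real_, converged = TRUE, groups = NULL,
                       df.residual = NA_integer_), class = "multistage")
  e0 <- excess_and_extra_risk(f0, 50)
  expect_identical(e0$added, e0$extra)
})

test_that("group summaries average per-worker risks with t-intervals", {
  fit <- benzene_cohort_lms()
  w <- data.frame(c_twa = c(2, 2, 4, 4, 10),
                  duration_years = c(1, 1, 2, 3, 1),
                  group = factor(c("a", "a", "b", "b", "c"),
                                 levels = c("a", "b", "c")))
  s <- group_risk_summary(w, fit)
  r <- risk_from_twa(fit, w$c_twa, w$duration_years)
  expect_equal(s$risk, c(mean(r[1:2]), mean(r[3:4]), r[5]))
  # identical exposures: zero-width interval
  expect_equal(s$ci_low[1], s$risk[1])
  expect_equal(s$ci_high[1], s$risk[1])
  # singleton group: interval undefined and flagged
  expect_true(is.na(s$ci_low[3]))
  expect_false(s$ci_defined[3])
  expect_true(all(s$ci_low[1:2] <= s$risk[1:2] &
                    s$risk[1:2] <= s$ci_high[1:2]))
  expect_error(group_risk_summary(w[, 1:2], fit), "group")
})

test_that("group means track the risk at the mean dose in the linear range", {
  fit <- benzene_cohort_lms()
  set.seed(3)
  dc <- rlnorm(200, log(5), 0.8)            # a1 * max(dc) << 0.01
  mean_risk <- mean(multistage_probability(fit, dc))
  risk_at_mean <- multistage_probability(fit, mean(dc))
  expect_lt(abs(mean_risk / risk_at_mean - 1), 0.005)
})

test_that("all reported risks exceed background under positive exposure", {
  fit <- benzene_cohort_lms()
  w <- data.frame(c_twa = runif(20, 0.1, 30), duration_years = runif(20, 0.1, 5),
                  group = factor(rep(c("g1", "g2"), 10)))
  s <- group_risk_summary(w, fit)
  expect_true(all(s$risk > fit$r))
})

test_that("trend test behaves at its edge cases", {
  same <- lapply(1:3, function(i) rep(2, 5))
  tt <- trend_test(same)
  expect_identical(tt$statistic, 0)
  expect_identical(tt$p_value, 1)
  expect_error(trend_test(list(1:3, 2:4)), "three ordered groups")
  expect_error(trend_test(list(1:3, numeric(0), 2:4, 3:5)), "at least one value")
})

test_that("trend test detects separated means and respects the null", {
  set.seed(21)
  sep <- lapply(1:4, function(j) rnorm(25, mean = 3 * j, sd = 1))
  expect_lt(trend_test(sep)$p_value, 1e-4)
  expect_gt(trend_test(sep)$slope_sign, 0)
  # stochastically ordered groups give ordered group summaries
  fit <- benzene_cohort_lms()
  w <- data.frame(
    c_twa = unlist(lapply(1:4, function(j) runif(20, j * 2, j * 2 + 1))),
    duration_years = 1,
    group = factor(rep(paste0("g", 1:4), each = 20)))
  s <- group_risk_summary(w, fit)
  expect_true(all(diff(s$risk) > 0))
})
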