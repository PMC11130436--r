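test_that("probability evaluation matches the closed form and its bounds", {
  fit <- benzene_cohort_lms()
  expect_identical(multistage_probability(fit, 0), fit$r)
  expect_equal(multistage_probability(fit, 388),
               lms_formula(4.32e-4, 1.38e-6, 388))
  grid <- seq(0, 1000, length.out = 101)
  p <- multistage_probability(fit, grid)
  expect_true(all(diff(p) >= 0))          # non-decreasing in dose
  expect_true(all(p >= fit$r & p < 1))
  expect_error(multistage_probability(fit, -1), "dose")
})

test_that("a saturated two-group design is solved exactly", {
  g <- dose_groups(c(0, 100), c(1000, 1000), c(10, 20))
  fit <- fit_multistage(g, degree = 1)
  # closed-form solution: r equals the zero-dose proportion and a1 solves
  # the exposed-group proportion
  expect_equal(fit$r, 0.01, tolerance = 1e-9)
  expect_equal(unname(fit$a[1]), -log(1 - (0.02 - 0.01) / 0.99) / 100,
               tolerance = 1e-9)
  expect_lt(max(abs(predict(fit) - g$n_cases / g$n_subjects)), 1e-9)
})

test_that("saturated fits reproduce monotone observed proportions", {
  # proportions are generated from a model with non-negative coefficients,
  # so the saturated solution is feasible under the constraints
  set.seed(11)
  for (k in 1:2) {  # degree 1 and 2
    for (rep in 1:3) {
      d <- c(0, sort(runif(k, 10, 100)))
      n <- sample(500:2000, k + 1, replace = TRUE)
      r <- runif(1, 0.02, 0.1)
      a <- runif(k, 0.1, 1) / max(d)^seq_len(k)
      x <- round(n * lms_formula_poly(r, a, d))
      g <- dose_groups(d, n, x)
      fit <- fit_multistage(g, degree = k)
      expect_lt(max(abs(predict(fit) - x / n)), 1e-9)
    }
  }
})

test_that("the MLE is at least as good as a brute-force grid search", {
  set.seed(101)
  for (i in 1:3) {
    g <- random_small_cohort()
    fit <- suppressWarnings(fit_multistage(g, degree = 1))
    a1 <- max(unname(fit$a[1]), 1e-6)
    oracle <- grid_best_loglik(g, r_range = c(1e-5, 0.2),
                               a_range = c(a1 / 5, a1 * 5))
    expect_gte(fit$loglik, oracle - 1e-6)
  }
})

test_that("flat dose-response collapses to the background", {
  g <- dose_groups(c(0, 50, 200), c(1000, 1000, 1000), c(20, 20, 20))
  fit <- fit_multistage(g, degree = 1)
  expect_lt(unname(fit$a[1]) * 200, 1e-6)  # no dose effect
  expect_equal(fit$r, 0.02, tolerance = 1e-4)
})

test_that("all-zero case counts pin the background to zero with a warning", {
  g <- dose_groups(c(0, 100), c(500, 500), c(0, 0))
  expect_warning(fit <- fit_multistage(g), "zero cases")
  expect_identical(fit$r, 0)
  expect_identical(unname(fit$a), 0)
  expect_equal(fit$loglik, 0)
})

test_that("identifiability and domain constraints are enforced", {
  g <- dose_groups(c(0, 65, 388), c(100, 100, 100), c(1, 2, 3))
  expect_error(fit_multistage(g, degree = 3), "identifiable")
  expect_error(fit_multistage(g, degree = 0), "degree")
  expect_error(fit_multistage(g[1, ], degree = 1), "two dose groups")
})

test_that("goodness of fit: df bookkeeping, saturation, exact fits", {
  # counts constructed to sit exactly on a degree-1 curve (r=0.2, chosen a):
  # observed equals expected, so both statistics vanish
  a <- -log(0.875) / 50
  p <- lms_formula(0.2, a, c(0, 50, 100))
  g <- dose_groups(c(0, 50, 100), c(1000, 1000, 1600),
                   round(c(1000, 1000, 1600) * p))
  fit <- fit_multistage(g, degree = 1)
  gof <- goodness_of_fit(fit)
  expect_equal(gof$df, 1L)
  expect_lt(gof$pearson, 1e-10)
  expect_lt(gof$deviance, 1e-10)
  expect_equal(gof$p_value, 1, tolerance = 1e-5)

  sat <- fit_multistage(dose_groups(c(0, 100), c(1000, 1000), c(10, 20)))
  expect_error(goodness_of_fit(sat), "saturated")

  g2 <- chinese_benzene_cohort()
  fit2 <- fit_multistage(g2)
  gof2 <- goodness_of_fit(fit2)
  expect_equal(gof2$df, nrow(g2) - 2L)
  # deviance equals twice the gap to the saturated log-likelihood
  sat_ll <- sum(dbinom(g2$n_cases, g2$n_subjects,
                       g2$n_cases / g2$n_subjects, log = TRUE))
  expect_equal(gof2$deviance, 2 * (sat_ll - fit2$loglik), tolerance = 1e-8)
  # Pearson variant exposed with its own p-value
  gofp <- goodness_of_fit(fit2, statistic = "pearson")
  expect_equal(gofp$chi_square, gofp$pearson)
  expect_gt(gofp$p_pearson, gofp$p_deviance)
})

test_that("degree selection prefers the best-fitting, lowest degree", {
  g <- chinese_benzene_cohort()
  best <- select_degree(g, max_degree = 1)
  expect_equal(best$degree, 1L)
  expect_s3_class(attr(best, "gof"), "multistage_gof")
  flat <- dose_groups(c(0, 50, 100, 200), rep(1000, 4), rep(20, 4))
  expect_equal(select_degree(flat, max_degree = 2)$degree, 1L)
})

test_that("model methods are coherent", {
  g <- chinese_benzene_cohort()
  fit <- fit_multistage(g)
  expect_named(coef(fit), c("r", "a1"))
  expect_equal(unname(predict(fit)), fitted(fit))
  expect_equal(predict(fit, dose = 5),
               multistage_probability(fit, 5))
  ll <- logLik(fit)
  expect_equal(attr(ll, "df"), 2L)
  expect_equal(as.numeric(ll), fit$loglik)
  expect_length(residuals(fit), 3)
  expect_length(residuals(fit, type = "deviance"), 3)
  s1 <- simulate(fit, nsim = 3, seed = 5)
  s2 <- simulate(fit, nsim = 3, seed = 5)
  expect_identical(s1, s2)
  expect_true(all(s1 <= g$n_subjects))
  expect_output(print(fit), "degree 1")
  expect_output(print(summary(fit)), "Goodness of fit")
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
})
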