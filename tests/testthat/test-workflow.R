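test_that("cohort fitting workflow reproduces the reference model", {
  out <- withr::local_tempfile(fileext = ".json")
  fit <- run_fit_cohort(chinese_benzene_cohort(), degree = 1, out = out)
  expect_equal(round(1e4 * fit$r, 2), 4.32)
  expect_equal(signif(unname(fit$a[1]), 2), 1.4e-6)
  js <- jsonlite::read_json(out)
  expect_equal(js$degree, 1L)
  expect_equal(js$r, fit$r)
  expect_equal(js$gof$df, 1L)
  expect_true(js$converged)
  # degree selection mode stores the GOF on the fit
  auto <- run_fit_cohort(chinese_benzene_cohort())
  expect_s3_class(attr(auto, "gof"), "multistage_gof")
})

test_that("cohort workflow rejects malformed input", {
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("dose_midpoint,n_subjects", "0,10"), bad)
  expect_error(run_fit_cohort(bad), "n_cases")
  g <- chinese_benzene_cohort()
  expect_error(run_fit_cohort(g, degree = 5), "identifiable")
})

test_that("assessment workflow produces a full risk table", {
  sim <- generate_workers(synthetic_config(seed = 17))
  outdir <- withr::local_tempdir()
  tab <- run_assess(sim$samples, sim$workers, out_dir = outdir)
  expect_equal(as.character(tab$group),
               c("<3", "3-5", "5-12", ">=12", "Total"))
  expect_true(all(c("risk_air", "risk_spma", "risk_ttma",
                    "risk_air_1e4", "ci_low_air", "ci_high_air")
                  %in% names(tab)))
  occupied <- tab$n > 1 & tab$group != "Total"
  expect_true(all(tab$risk_air[occupied] > benzene_cohort_lms()$r))
  expect_true(all(tab$ci_low_air[occupied] <= tab$risk_air[occupied] &
                    tab$risk_air[occupied] <= tab$ci_high_air[occupied]))
  tr <- attr(tab, "trend")
  expect_named(tr, c("air", "spma", "ttma"))
  expect_true(all(sapply(tr, function(t) t$p_value >= 0 && t$p_value <= 1)))
  bl <- attr(tab, "below_lod")
  expect_equal(bl$n_workers, 5L)
  expect_gt(bl$risk_at_median, benzene_cohort_lms()$r)
  expect_true(file.exists(file.path(outdir, "risk_table.csv")))
  expect_true(file.exists(file.path(outdir, "qc_report.json")))
  expect_true(file.exists(file.path(outdir, "manifest.json")))
  # rerunning reproduces the table exactly
  expect_equal(run_assess(sim$samples, sim$workers), tab,
               ignore_attr = TRUE)
})

test_that("assessment workflow handles empty and malformed input", {
  empty <- data.frame(worker_id = character(), sample_round = integer(),
                      air_benzene_mg_m3 = numeric(), spma_ug_gcr = numeric(),
                      ttma_ug_gcr = numeric(), creatinine_g_l = numeric(),
                      smoker = integer())
  workers <- data.frame(worker_id = character(), duration_years = numeric(),
                        smoker = integer())
  expect_warning(out <- run_assess(empty, workers), "no input")
  expect_equal(nrow(out), 0L)
  sim <- generate_workers(synthetic_config(seed = 17))
  expect_error(run_assess(sim$samples[, -3], sim$workers), "air_benzene")
  # workers all below LOD: air path empty, biomarker path populated
  bl_ids <- sim$workers$worker_id[sim$workers$below_lod]
  bl_samples <- sim$samples[sim$samples$worker_id %in% bl_ids, ]
  bl_workers <- sim$workers[sim$workers$below_lod, ]
  expect_warning(tab <- run_assess(bl_samples, bl_workers), "valid air")
  expect_equal(attr(tab, "below_lod")$n_workers, 5L)
})

test_that("model comparison workflow aligns the three models per group", {
  sim <- generate_workers(synthetic_config(seed = 17))
  cmp <- run_compare(sim$samples, sim$workers)
  expect_true(all(c("risk_lms", "epa_low", "epa_high", "singapore_value",
                    "singapore_label") %in% names(cmp)))
  expect_true(all(cmp$epa_low <= cmp$epa_high))
  expect_true(all(cmp$singapore_value >= 1 & cmp$singapore_value <= 5))
  # collapsing the IUR range collapses the EPA columns
  epa1 <- epa_defaults(); epa1$iur_high <- epa1$iur_low
  cmp1 <- run_compare(sim$samples, sim$workers, epa = epa1)
  expect_equal(cmp1$epa_low, cmp1$epa_high)
  # a lower OEL pushes exposure ratings up
  cmp2 <- run_compare(sim$samples, sim$workers, oel = 0.3)
  expect_true(all(cmp2$singapore_er >= cmp$singapore_er))
})
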