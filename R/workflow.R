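# End-to-end orchestration: fit the cohort model, assess workers, compare
# the three risk models. These functions accept file paths or data frames,
# and optionally write CSV/JSON artifacts.

read_table_checked <- function(x, required, what) {
  if (is.character(x) && length(x) == 1L) {
    x <- tryCatch(utils::read.csv(x, stringsAsFactors = FALSE),
                  error = function(e) stop("failed to parse ", what, ": ",
                                           conditionMessage(e), call. = FALSE))
  }
  if (!is.data.frame(x)) stop(what, " must be a data frame or CSV path",
                              call. = FALSE)
  missing <- setdiff(required, names(x))
  if (length(missing))
    stop(what, " lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  x
}

run_manifest <- function(inputs, options) {
  list(
    package = "benzrisk",
    version = as.character(utils::packageVersion("benzrisk")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = inputs, options = options
  )
}

#' Fit the multistage model to a cohort file
#'
#' Reads (or takes) a grouped-cohort table, fits the multistage model —
#' either at a fixed degree or selecting the degree by goodness of fit —
#' and optionally writes the fit as JSON.
#'
#' @param cohort Path to a CSV with header
#'   \code{dose_midpoint,n_subjects,n_cases}, or an equivalent data frame.
#' @param degree Fixed degree, or \code{NULL} (default) to pick the degree
#'   in \code{1..max_degree} with the best goodness-of-fit p-value.
#' @param max_degree Upper bound for degree selection.
#' @param out Optional path for a JSON artifact with the fitted parameters
#'   and GOF.
#' @return The \code{"multistage"} fit, with its [goodness_of_fit()] result
#'   as attribute \code{"gof"}.
#' @examples
#' fit <- run_fit_cohort(chinese_benzene_cohort())
#' coef(fit)
#' @export
run_fit_cohort <- function(cohort, degree = NULL, max_degree = 2L,
                           out = NULL) {
  groups <- as_dose_groups(read_table_checked(
    cohort, c("dose_midpoint", "n_subjects", "n_cases"), "cohort table"))
  fit <- if (is.null(degree)) select_degree(groups, max_degree = max_degree)
         else structure(fit_multistage(groups, degree = degree), gof = NULL)
  if (!isTRUE(fit$converged))
    stop("multistage fit did not converge", call. = FALSE)
  gof <- attr(fit, "gof")
  if (is.null(gof) && fit$df.residual > 0) {
    gof <- goodness_of_fit(fit)
    attr(fit, "gof") <- gof
  }
  if (!is.null(out)) {
    payload <- list(
      degree = fit$degree, r = fit$r, a = as.numeric(fit$a),
      loglik = fit$loglik, converged = fit$converged,
      gof = if (!is.null(gof)) list(statistic = gof$statistic,
                                    chi2 = gof$chi_square, df = gof$df,
                                    p = gof$p_value),
      manifest = run_manifest(
        list(groups = nrow(groups)),
        list(degree = fit$degree, max_degree = max_degree))
    )
    jsonlite::write_json(payload, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  fit
}

summarize_worker_risks <- function(risk, grp, dc, conf_level = 0.95) {
  do.call(rbind, lapply(levels(grp), function(g) {
    rr <- risk[grp == g]; n <- length(rr)
    if (n == 0)
      return(data.frame(group = g, n = 0L, mean_ce = NA_real_,
                        risk = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_))
    m <- mean(rr)
    if (n >= 2) {
      se <- stats::sd(rr) / sqrt(n)
      tq <- stats::qt(1 - (1 - conf_level) / 2, n - 1)
      lo <- m - tq * se; hi <- m + tq * se
    } else lo <- hi <- NA_real_
    data.frame(group = g, n = n, mean_ce = mean(dc[grp == g]),
               risk = m, ci_low = lo, ci_high = hi)
  }))
}

#' Assess worker leukemia risks from air and biomarker measurements
#'
#' Full assessment pipeline: QC-filter the per-round samples, aggregate to
#' per-worker time-weighted averages and cumulative exposures, assign
#' exposure groups, and summarize the multistage leukemia risk per group
#' three ways — from airborne benzene, from urinary S-PMA and from urinary
#' t,t-MA — with t-intervals, a "Total" row, and an ANOVA trend test per
#' column. Below-LOD workers are assessed separately from their t,t-MA and
#' reported in attribute \code{"below_lod"}.
#'
#' Biomarker risks use the published regression coefficients (not refitted
#' values) unless other \code{"loglog_fit"} objects are supplied: each valid
#' sample's metabolite level is inverted to an equivalent air concentration,
#' evaluated under the model with the worker's duration, and the per-sample
#' risks are averaged within worker before the group summary.
#'
#' @param samples Per-round sample CSV path or data frame (columns
#'   \code{worker_id,sample_round,air_benzene_mg_m3,spma_ug_gcr,ttma_ug_gcr,creatinine_g_l,smoker}).
#' @param workers Per-worker CSV path or data frame (columns
#'   \code{worker_id,duration_years,smoker}).
#' @param fit Multistage model (default [benzene_cohort_lms()]).
#' @param spma_fit,ttma_fit \code{"loglog_fit"} calibrations (defaults:
#'   published coefficient sets).
#' @param boundaries Group boundaries for [assign_groups()].
#' @param lod Air limit of detection, mg/m^3.
#' @param conf_level Confidence level of the t-intervals.
#' @param out_dir Optional directory: writes \code{risk_table.csv},
#'   \code{qc_report.json} and \code{manifest.json}.
#' @return Data frame with one row per group plus a \code{"Total"} row:
#'   \code{group}, \code{n}, \code{mean_ce}, and for each of
#'   air/spma/ttma the risk, CI bounds and the display value in 1e-4 units
#'   (2 decimals). Attributes: \code{"trend"} (list of [trend_test()]
#'   results), \code{"qc_report"}, \code{"below_lod"}, \code{"exposure"}
#'   (the per-worker table).
#' @export
run_assess <- function(samples, workers, fit = benzene_cohort_lms(),
                       spma_fit = metabolite_coefs("spma"),
                       ttma_fit = metabolite_coefs("ttma"),
                       boundaries = c(3, 5, 12), lod = 0.05,
                       conf_level = 0.95, out_dir = NULL) {
  samples <- read_table_checked(
    samples,
    c("worker_id", "air_benzene_mg_m3", "spma_ug_gcr", "ttma_ug_gcr",
      "creatinine_g_l"),
    "sample table")
  workers <- read_table_checked(
    workers, c("worker_id", "duration_years", "smoker"), "worker table")
  if (nrow(samples) == 0L || nrow(workers) == 0L) {
    warning("no input records; returning empty assessment", call. = FALSE)
    return(data.frame())
  }
  qc <- qc_filter(samples, lod = lod)
  expo <- aggregate_workers(qc$valid, workers)
  if (nrow(expo) == 0L) {
    warning("no worker has a valid air sample; see attribute 'below_lod'",
            call. = FALSE)
  }
  expo <- assign_groups(expo, boundaries)

  dur <- expo$duration_years[match(qc$valid$worker_id, expo$worker_id)]
  worker_mean_risk <- function(mfit, column) {
    rs <- risk_from_metabolite(fit, mfit, qc$valid[[column]],
                               smoker = qc$valid$smoker, t = dur)
    as.numeric(tapply(rs, qc$valid$worker_id, mean)[expo$worker_id])
  }
  risks <- list(
    air = risk_from_twa(fit, expo$c_twa, expo$duration_years),
    spma = worker_mean_risk(spma_fit, "spma_ug_gcr"),
    ttma = worker_mean_risk(ttma_fit, "ttma_ug_gcr")
  )

  grp <- expo$group
  tabs <- lapply(risks, summarize_worker_risks, grp = grp, dc = expo$dc,
                 conf_level = conf_level)
  out <- tabs$air[c("group", "n", "mean_ce")]
  for (nm in names(tabs)) {
    t1 <- tabs[[nm]]
    out[[paste0("risk_", nm)]] <- t1$risk
    out[[paste0("ci_low_", nm)]] <- t1$ci_low
    out[[paste0("ci_high_", nm)]] <- t1$ci_high
    out[[paste0("risk_", nm, "_1e4")]] <- risk_x1e4(t1$risk)
  }
  # "Total" row over all assessable workers
  total <- data.frame(group = "Total", n = nrow(expo),
                      mean_ce = mean(expo$dc))
  for (nm in names(risks)) {
    rr <- risks[[nm]]
    m <- mean(rr)
    se <- if (length(rr) >= 2) stats::sd(rr) / sqrt(length(rr)) else NA
    tq <- stats::qt(1 - (1 - conf_level) / 2, max(length(rr) - 1, 1))
    total[[paste0("risk_", nm)]] <- m
    total[[paste0("ci_low_", nm)]] <- m - tq * se
    total[[paste0("ci_high_", nm)]] <- m + tq * se
    total[[paste0("risk_", nm, "_1e4")]] <- risk_x1e4(m)
  }
  out <- rbind(out, total)
  rownames(out) <- NULL

  occupied <- levels(grp)[table(grp) > 0]
  attr(out, "trend") <- if (length(occupied) >= 3)
    lapply(risks, function(rr) trend_test(split(rr, droplevels(grp)))) else
    NULL

  # below-LOD workers: biomarker-only path via t,t-MA
  bl <- qc$below_lod
  bl_summary <- NULL
  if (nrow(bl)) {
    bdur <- workers$duration_years[match(bl$worker_id, workers$worker_id)]
    bl_risk <- risk_from_metabolite(fit, ttma_fit, bl$ttma_ug_gcr,
                                    smoker = bl$smoker, t = bdur)
    ttma_by_worker <- tapply(bl$ttma_ug_gcr, bl$worker_id, mean)
    med <- stats::median(as.numeric(ttma_by_worker))
    bl_summary <- list(
      n_workers = length(ttma_by_worker),
      median_ttma = med,
      mean_duration = mean(tapply(bdur, bl$worker_id, mean)),
      risk_at_median = risk_from_metabolite(
        fit, ttma_fit, med, smoker = 0,
        t = mean(tapply(bdur, bl$worker_id, mean))),
      per_sample_risk = bl_risk
    )
  }
  attr(out, "below_lod") <- bl_summary
  attr(out, "qc_report") <- qc$report
  attr(out, "exposure") <- expo

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out, file.path(out_dir, "risk_table.csv"),
                     row.names = FALSE)
    jsonlite::write_json(qc$report, file.path(out_dir, "qc_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(
      run_manifest(list(samples = nrow(samples), workers = nrow(workers)),
                   list(boundaries = boundaries, lod = lod,
                        fit = as.list(coef(fit)))),
      file.path(out_dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' Compare the multistage, EPA and Singapore risk models per group
#'
#' For each exposure group: the multistage risk summarized over workers, the
#' EPA inhalation-unit-risk range computed from the group's mean airborne
#' concentration and mean working duration, and the Singapore
#' semi-quantitative rating from the group's mean concentration against the
#' occupational exposure limit.
#'
#' @inheritParams run_assess
#' @param epa EPA parameter list (see [epa_defaults()]); set
#'   \code{iur_low == iur_high} to collapse the range to a point.
#' @param hr Singapore hazard rating (default 5).
#' @param oel Occupational exposure limit, mg/m^3 (default 3).
#' @return Data frame, one row per occupied group: \code{group}, \code{n},
#'   \code{c_twa}, \code{mean_ce}, \code{duration}, \code{risk_lms} (+
#'   display column), \code{epa_low}, \code{epa_high} (+ display columns,
#'   1 decimal in 1e-4 units), \code{singapore_er},
#'   \code{singapore_value}, \code{singapore_label}.
#' @export
run_compare <- function(samples, workers, fit = benzene_cohort_lms(),
                        epa = epa_defaults(), hr = 5, oel = 3,
                        boundaries = c(3, 5, 12), lod = 0.05,
                        out_dir = NULL) {
  samples <- read_table_checked(
    samples, c("worker_id", "air_benzene_mg_m3", "ttma_ug_gcr",
               "creatinine_g_l"), "sample table")
  workers <- read_table_checked(
    workers, c("worker_id", "duration_years", "smoker"), "worker table")
  qc <- qc_filter(samples, lod = lod)
  expo <- assign_groups(aggregate_workers(qc$valid, workers), boundaries)
  lms <- group_risk_summary(expo, fit)
  keep <- lms$n > 0
  out <- do.call(rbind, lapply(which(keep), function(i) {
    g <- as.character(lms$group[i])
    sel <- expo$group == g
    ctwa <- mean(expo$c_twa[sel]); dur <- mean(expo$duration_years[sel])
    ep <- epa_group_risk(ctwa, dur, epa)
    sg <- singapore_from_exposure(ctwa, oel = oel, hr = hr)
    data.frame(group = g, n = lms$n[i], c_twa = ctwa,
               mean_ce = lms$mean_ce[i], duration = dur,
               risk_lms = lms$risk[i],
               risk_lms_1e4 = risk_x1e4(lms$risk[i]),
               epa_low = ep$risk_low, epa_high = ep$risk_high,
               epa_low_1e4 = risk_x1e4(ep$risk_low, 1),
               epa_high_1e4 = risk_x1e4(ep$risk_high, 1),
               singapore_er = sg$er, singapore_value = sg$risk_value,
               singapore_label = sg$label)
  }))
  rownames(out) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out, file.path(out_dir, "model_comparison.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      run_manifest(list(samples = nrow(samples), workers = nrow(workers)),
                   list(epa = epa, hr = hr, oel = oel,
                        boundaries = boundaries,
                        fit = as.list(coef(fit)))),
      file.path(out_dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
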