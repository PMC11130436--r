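# Sample quality control and per-worker exposure aggregation.

#' Quality-control filter for per-sample measurements
#'
#' Applies the study's sample validity rules to per-round measurements:
#' \enumerate{
#'   \item samples with missing creatinine are excluded;
#'   \item samples with urinary creatinine < 0.3 g/L or > 3 g/L are excluded
#'     (unreliable dilution correction);
#'   \item samples with airborne benzene below the limit of detection are
#'     flagged \emph{below-LOD} and routed to biomarker-only assessment —
#'     they are neither imputed nor discarded;
#'   \item samples with airborne benzene < 3 mg/m^3 but t,t-MA above
#'     1,000 ug/g creatinine are excluded (dietary sorbic-acid
#'     contamination of t,t-MA).
#' }
#' Rules apply in that order, so e.g. a below-LOD sample with high t,t-MA is
#' kept on the biomarker path rather than excluded by the dietary rule.
#'
#' @param samples Data frame with columns \code{worker_id},
#'   \code{air_benzene_mg_m3}, \code{ttma_ug_gcr}, \code{creatinine_g_l}
#'   (other columns are carried through).
#' @param lod Airborne benzene limit of detection, mg/m^3 (default 0.05).
#' @return List with elements \code{valid} (samples passing all rules),
#'   \code{below_lod} (LOD-flagged samples), \code{excluded}, and
#'   \code{report}: counts \code{n_input}, \code{n_valid},
#'   \code{n_excluded_missing}, \code{n_excluded_creatinine},
#'   \code{n_excluded_ttma_rule}, \code{n_below_lod} (summing to
#'   \code{n_input}).
#' @export
qc_filter <- function(samples, lod = 0.05) {
  need <- c("air_benzene_mg_m3", "ttma_ug_gcr", "creatinine_g_l")
  missing <- setdiff(need, names(samples))
  if (length(missing))
    stop("samples lack column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  n_input <- nrow(samples)
  status <- rep("valid", n_input)
  cr <- samples$creatinine_g_l
  status[is.na(cr)] <- "missing"
  status[status == "valid" & (cr < 0.3 | cr > 3)] <- "creatinine"
  status[status == "valid" & samples$air_benzene_mg_m3 < lod] <- "below_lod"
  status[status == "valid" & samples$air_benzene_mg_m3 < 3 &
           samples$ttma_ug_gcr > 1000] <- "ttma_rule"
  report <- list(
    n_input = n_input,
    n_valid = sum(status == "valid"),
    n_excluded_missing = sum(status == "missing"),
    n_excluded_creatinine = sum(status == "creatinine"),
    n_excluded_ttma_rule = sum(status == "ttma_rule"),
    n_below_lod = sum(status == "below_lod")
  )
  list(valid = samples[status == "valid", , drop = FALSE],
       below_lod = samples[status == "below_lod", , drop = FALSE],
       excluded = samples[status %in% c("missing", "creatinine", "ttma_rule"),
                          , drop = FALSE],
       report = report)
}

#' Aggregate valid samples into per-worker exposures
#'
#' The worker's time-weighted average concentration is the unweighted
#' arithmetic mean of that worker's valid air samples, and the cumulative
#' exposure is \eqn{D_c = C_{TWA} \times T} with the worker's working
#' duration \eqn{T}. Workers without any valid air sample are omitted from
#' the result and listed in attribute \code{"biomarker_only"} (assess them
#' from their urinary metabolites instead).
#'
#' @param valid_samples Valid samples, as returned in \code{$valid} by
#'   [qc_filter()] (needs \code{worker_id} and \code{air_benzene_mg_m3}).
#' @param workers Per-worker data frame with columns \code{worker_id},
#'   \code{duration_years} (> 0) and \code{smoker}.
#' @return Data frame with one row per assessable worker:
#'   \code{worker_id}, \code{n_samples}, \code{c_twa},
#'   \code{duration_years}, \code{dc}, \code{smoker}.
#' @export
aggregate_workers <- function(valid_samples, workers) {
  need_w <- c("worker_id", "duration_years", "smoker")
  missing <- setdiff(need_w, names(workers))
  if (length(missing))
    stop("workers lack column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (any(workers$duration_years <= 0))
    stop("working duration must be > 0", call. = FALSE)
  means <- tapply(valid_samples$air_benzene_mg_m3, valid_samples$worker_id,
                  mean)
  counts <- tapply(valid_samples$air_benzene_mg_m3, valid_samples$worker_id,
                   length)
  idx <- match(workers$worker_id, names(means))
  out <- data.frame(
    worker_id = workers$worker_id,
    n_samples = as.integer(counts[idx]),
    c_twa = as.numeric(means[idx]),
    duration_years = workers$duration_years,
    smoker = workers$smoker
  )
  drop <- is.na(out$c_twa)
  res <- out[!drop, , drop = FALSE]
  res$dc <- res$c_twa * res$duration_years
  rownames(res) <- NULL
  attr(res, "biomarker_only") <- workers$worker_id[drop]
  res
}

#' Assign workers to cumulative-exposure groups
#'
#' Bins cumulative exposure into half-open intervals defined by the given
#' boundaries; the defaults are the study's rounded quartiles, giving the
#' groups [0,3), [3,5), [5,12) and [12, Inf) mg/m^3-year. Boundaries are
#' left-closed, so \eqn{D_c = 3} falls in "3-5".
#'
#' @param workers Data frame with a \code{dc} column (mg/m^3-year, >= 0).
#' @param boundaries Strictly increasing positive cut points (default
#'   \code{c(3, 5, 12)}), or \code{"quartiles"} to use the data's quartiles
#'   rounded to integers.
#' @return \code{workers} with an ordered factor column \code{group}
#'   labelled \code{"<b1"}, \code{"b1-b2"}, ..., \code{">=bk"}.
#' @examples
#' assign_groups(data.frame(dc = c(1.62, 3, 11.999, 86.79)))
#' @export
assign_groups <- function(workers, boundaries = c(3, 5, 12)) {
  if (is.null(workers$dc)) stop("workers need a 'dc' column", call. = FALSE)
  if (any(workers$dc < 0)) stop("cumulative exposure must be >= 0",
                                call. = FALSE)
  if (identical(boundaries, "quartiles")) {
    boundaries <- unique(round(stats::quantile(workers$dc,
                                               c(0.25, 0.5, 0.75))))
    boundaries <- boundaries[boundaries > 0]
  }
  if (length(boundaries) < 1L || any(diff(boundaries) <= 0) ||
      any(boundaries <= 0))
    stop("boundaries must be strictly increasing and positive",
         call. = FALSE)
  k <- length(boundaries)
  labels <- c(paste0("<", boundaries[1]),
              if (k > 1) paste0(boundaries[-k], "-", boundaries[-1]),
              paste0(">=", boundaries[k]))
  workers$group <- cut(workers$dc, breaks = c(0, boundaries, Inf),
                       labels = labels, right = FALSE,
                       include.lowest = TRUE, ordered_result = TRUE)
  workers
}
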