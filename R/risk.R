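#' Leukemia risk from a time-weighted average exposure
#'
#' Evaluates the multistage model at the cumulative exposure
#' \eqn{D_c = C_{TWA} \times T}: the risk after \code{t} years of work at an
#' airborne benzene concentration of \code{c_twa} mg/m^3. Only the product
#' matters, so \code{risk_from_twa(fit, c, t)} equals
#' \code{risk_from_twa(fit, c * t, 1)}.
#'
#' @param fit A \code{"multistage"} fit.
#' @param c_twa Time-weighted average airborne concentration, mg/m^3 (>= 0).
#' @param t Working duration, years (>= 0). Recycled against \code{c_twa}.
#' @return Vector of risk probabilities.
#' @examples
#' risk_from_twa(benzene_cohort_lms(), c_twa = 2.31, t = 0.76)
#' @export
risk_from_twa <- function(fit, c_twa, t) {
  if (any(!is.finite(c_twa)) || any(c_twa < 0))
    stop("c_twa must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(t)) || any(t < 0))
    stop("t must be finite and >= 0", call. = FALSE)
  multistage_probability(fit, c_twa * t)
}

#' Added and extra risk over background
#'
#' Decomposes the multistage response at a dose into the added risk
#' \eqn{P(d) - r} and the extra risk \eqn{(P(d) - r)/(1 - r)} (the added
#' risk rescaled to the background-free fraction of the population).
#'
#' @inheritParams multistage_probability
#' @return A data frame with columns \code{dose}, \code{risk} (\eqn{P(d)}),
#'   \code{added} and \code{extra}.
#' @examples
#' excess_and_extra_risk(benzene_cohort_lms(), 86.79)
#' @export
excess_and_extra_risk <- function(fit, dose) {
  p <- multistage_probability(fit, dose)
  data.frame(dose = dose, risk = p, added = p - fit$r,
             extra = (p - fit$r) / (1 - fit$r))
}

#' Per-group risk summaries for exposed workers
#'
#' Computes every worker's risk via [risk_from_twa()] and summarizes each
#' exposure group by the mean risk and a t-interval:
#' mean +/- t(1-alpha/2, n-1) * SE. Groups with fewer than two workers get
#' \code{NA} limits and are flagged in the \code{ci_defined} column.
#'
#' @param workers Data frame with columns \code{c_twa} (mg/m^3),
#'   \code{duration_years} and \code{group} (factor; its level order defines
#'   the group order). A precomputed \code{dc} column, if present, is
#'   checked against \code{c_twa * duration_years}.
#' @param fit A \code{"multistage"} fit.
#' @param conf_level Confidence level of the t-interval (default 0.95).
#' @return Data frame, one row per group: \code{group}, \code{n},
#'   \code{mean_ce} (mean cumulative exposure, mg/m^3-year), \code{risk},
#'   \code{ci_low}, \code{ci_high}, \code{ci_defined}.
#' @export
group_risk_summary <- function(workers, fit, conf_level = 0.95) {
  need <- c("c_twa", "duration_years", "group")
  missing <- setdiff(need, names(workers))
  if (length(missing))
    stop("workers lack column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (anyNA(workers$group)) stop("every worker must be assigned a group",
                                 call. = FALSE)
  dc <- workers$c_twa * workers$duration_years
  if (!is.null(workers$dc) &&
      any(abs(workers$dc - dc) > 1e-12 * pmax(dc, 1)))
    stop("dc column inconsistent with c_twa * duration_years", call. = FALSE)
  risk <- risk_from_twa(fit, workers$c_twa, workers$duration_years)
  grp <- if (is.factor(workers$group)) workers$group else factor(workers$group)
  out <- do.call(rbind, lapply(levels(grp), function(g) {
    rr <- risk[grp == g]
    n <- length(rr)
    m <- mean(rr)
    if (n >= 2) {
      se <- stats::sd(rr) / sqrt(n)
      tq <- stats::qt(1 - (1 - conf_level) / 2, n - 1)
      lo <- m - tq * se; hi <- m + tq * se
    } else lo <- hi <- NA_real_
    data.frame(group = g, n = n, mean_ce = mean(dc[grp == g]),
               risk = m, ci_low = lo, ci_high = hi, ci_defined = n >= 2)
  }))
  out$group <- factor(out$group, levels = levels(grp))
  rownames(out) <- NULL
  out
}

#' ANOVA linear trend test across ordered groups
#'
#' One-way ANOVA linear-contrast test with equally spaced scores over the
#' group rank: with group means \eqn{\bar y_j} and centred scores
#' \eqn{c_j}, the contrast \eqn{L = \sum_j c_j \bar y_j} is tested with
#' \eqn{t = L / \sqrt{MSE \sum_j c_j^2 / n_j}} on \eqn{N - k} degrees of
#' freedom (two-sided).
#'
#' @param group_values List of numeric vectors, one per group, in increasing
#'   exposure order (>= 3 groups, each non-empty).
#' @return List of class \code{"trend_test"}: \code{statistic} (t),
#'   \code{f_statistic}, \code{df}, \code{p_value}, \code{slope_sign}.
#' @examples
#' set.seed(1)
#' trend_test(lapply(1:4, function(j) rnorm(20, mean = j)))
#' @export
trend_test <- function(group_values) {
  if (!is.list(group_values) || length(group_values) < 3L)
    stop("at least three ordered groups are required", call. = FALSE)
  n <- vapply(group_values, length, integer(1))
  if (any(n == 0L)) stop("every group must contain at least one value",
                         call. = FALSE)
  k <- length(group_values)
  means <- vapply(group_values, mean, numeric(1))
  scores <- seq_len(k) - (k + 1) / 2
  L <- sum(scores * means)
  N <- sum(n)
  sse <- sum(vapply(group_values,
                    function(v) sum((v - mean(v))^2), numeric(1)))
  df <- N - k
  if (df <= 0L) stop("no residual degrees of freedom for the trend test",
                     call. = FALSE)
  mse <- sse / df
  denom2 <- mse * sum(scores^2 / n)
  if (L == 0) {
    tstat <- 0; p <- 1
  } else if (denom2 == 0) {
    tstat <- sign(L) * Inf; p <- 0
  } else {
    tstat <- L / sqrt(denom2)
    p <- 2 * stats::pt(-abs(tstat), df)
  }
  structure(list(statistic = tstat, f_statistic = tstat^2, df = df,
                 p_value = p, slope_sign = sign(L)),
            class = "trend_test")
}

#' @export
print.trend_test <- function(x, ...) {
  cat(sprintf("ANOVA linear trend: t = %.4f (df = %d), p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}
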