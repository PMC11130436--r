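# P(d) = r + (1 - r) * (1 - exp(-sum_i a_i d^i)); a_i >= 0, 0 <= r < 1.
ms_prob <- function(r, a, dose) {
  r <- unname(r); a <- unname(a)
  k <- length(a)
  s <- rep(0, length(dose))
  for (i in seq_len(k)) s <- s + a[i] * dose^i
  r + (1 - r) * (1 - exp(-s))
}

ms_loglik <- function(r, a, d, n, x) {
  p <- ms_prob(r, a, d)
  # binomial log-likelihood; p = 0 with x > 0 (or p = 1 with x < n) -> -Inf
  sum(stats::dbinom(x, n, pmin(pmax(p, 0), 1), log = TRUE))
}

#' Fit the linearized multistage model to grouped quantal data
#'
#' Constrained binomial maximum-likelihood fit of the multistage cancer
#' dose-response model
#' \deqn{P(d) = r + (1 - r)\,(1 - \exp(-\textstyle\sum_{i=1}^k a_i d^i))}
#' to grouped incidence data, with \eqn{0 \le r < 1} (background response)
#' and all stage coefficients \eqn{a_i \ge 0}. This is the quantal
#' dichotomous-multistage convention used by benchmark-dose software: each
#' dose group contributes a binomial likelihood term for its observed case
#' count.
#'
#' The likelihood is maximized by multi-start quasi-Newton optimization on an
#' unconstrained scale (logit \eqn{r}, log \eqn{a_i}) with a box-constrained
#' fallback on the natural scale, so coefficients can land exactly on the
#' \eqn{a_i = 0} boundary. When the model is saturated (number of groups
#' equals number of parameters) and the observed proportions are
#' non-decreasing in dose, the exact solution that reproduces the observed
#' proportions is used directly.
#'
#' @param groups A [dose_groups()] table (or a data frame with columns
#'   \code{dose_midpoint}, \code{n_subjects}, \code{n_cases}).
#' @param degree Polynomial degree \eqn{k \ge 1} (number of stages).
#'   \code{degree + 1} parameters are estimated, so \code{degree + 1} must
#'   not exceed the number of groups.
#' @param n_starts Number of deterministic multi-start points (default 5).
#' @return An object of class \code{"multistage"}: a list with elements
#'   \code{r}, \code{a} (named \code{a1..ak}), \code{degree},
#'   \code{loglik}, \code{converged}, \code{groups}, \code{df.residual}.
#'   Methods: \code{print}, \code{summary}, \code{coef}, \code{predict},
#'   \code{fitted}, \code{residuals}, \code{logLik}, \code{simulate},
#'   \code{plot}.
#' @seealso [goodness_of_fit()], [select_degree()], [multistage_probability()]
#' @examples
#' fit <- fit_multistage(chinese_benzene_cohort(), degree = 1)
#' coef(fit)
#' goodness_of_fit(fit)
#' @export
fit_multistage <- function(groups, degree = 1L, n_starts = 5L) {
  groups <- as_dose_groups(groups)
  degree <- as.integer(degree)
  d <- groups$dose_midpoint; n <- groups$n_subjects; x <- groups$n_cases
  if (nrow(groups) < 2L)
    stop("at least two dose groups are required", call. = FALSE)
  if (degree < 1L) stop("degree must be >= 1", call. = FALSE)
  if (degree + 1L > nrow(groups))
    stop("degree + 1 parameters for ", nrow(groups),
         " groups: model not identifiable", call. = FALSE)

  new_fit <- function(r, a, converged) {
    structure(list(
      r = r, a = stats::setNames(a, paste0("a", seq_len(degree))),
      degree = degree, loglik = ms_loglik(r, a, d, n, x),
      converged = converged, groups = groups,
      df.residual = nrow(groups) - (degree + 1L),
      call = match.call(fit_multistage, sys.call(-1L))
    ), class = "multistage")
  }

  if (all(x == 0)) {
    warning("all groups have zero cases; background r pinned to 0",
            call. = FALSE)
    return(new_fit(0, rep(0, degree), TRUE))
  }

  obs <- x / n
  cand <- list()  # candidate solutions: list(r, a, value, ok)

  # exact saturated solution when it is feasible (monotone proportions,
  # zero-dose group present): fitted probabilities equal observed ones
  if (nrow(groups) == degree + 1L && any(d == 0)) {
    r0 <- obs[d == 0]
    pos <- d > 0
    q <- (obs[pos] - r0) / (1 - r0)
    if (all(q >= 0) && all(q < 1)) {
      y <- -log(1 - q)
      V <- outer(d[pos], seq_len(degree), `^`)
      a_ex <- tryCatch(solve(V, y), error = function(e) NULL)
      if (!is.null(a_ex) && all(a_ex >= 0))
        cand[[length(cand) + 1L]] <- list(r = r0, a = a_ex, ok = TRUE)
    }
  }

  # deterministic multi-starts around a crude moment guess
  r_guess <- max(min(obs[which.min(d)], 1 - 1e-6), 1e-7)
  top <- max(obs) ; dmax <- max(d[d > 0], 1)
  slope <- max((top - r_guess) / (1 - r_guess), 1e-8)
  a_guess <- -log(max(1 - slope, 1e-12)) / dmax^seq_len(degree)
  scales <- c(1, 0.2, 5, 0.05, 20)[seq_len(max(1L, min(n_starts, 5L)))]
  lower <- c(1e-12, rep(0, degree))
  upper <- c(1 - 1e-12, rep(Inf, degree))

  for (s in scales) {
    start <- c(min(max(r_guess * s, 1e-10), 0.5), pmax(a_guess * s, 1e-30))
    # box-constrained natural-scale pass (reaches a_i = 0 exactly)
    nb <- tryCatch(stats::nlminb(
      start, function(p) -ms_loglik(p[1], p[-1], d, n, x),
      lower = lower, upper = upper,
      control = list(iter.max = 2000, eval.max = 4000,
                     abs.tol = 0, rel.tol = 1e-14)
    ), error = function(e) NULL)
    if (!is.null(nb))
      cand[[length(cand) + 1L]] <- list(r = nb$par[1], a = pmax(nb$par[-1], 0),
                                        ok = nb$convergence == 0)
    # unconstrained-scale pass (logit r, log a)
    th0 <- c(stats::qlogis(start[1]), log(pmax(start[-1], 1e-30)))
    nll_t <- function(th) -ms_loglik(stats::plogis(th[1]), exp(th[-1]), d, n, x)
    ob <- tryCatch(
      stats::optim(th0, nll_t, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(ob))
      cand[[length(cand) + 1L]] <- list(r = stats::plogis(ob$par[1]),
                                        a = exp(ob$par[-1]),
                                        ok = ob$convergence == 0)
  }

  if (!length(cand)) stop("multistage optimization failed", call. = FALSE)
  # Nelder-Mead polish of the current best interior candidate
  ll0 <- vapply(cand, function(cc) ms_loglik(cc$r, cc$a, d, n, x), numeric(1))
  bb <- cand[[which.max(ll0)]]
  if (bb$r > 0 && all(bb$a > 0)) {
    nll_t <- function(th) -ms_loglik(stats::plogis(th[1]), exp(th[-1]), d, n, x)
    ob <- tryCatch(
      stats::optim(c(stats::qlogis(bb$r), log(bb$a)), nll_t,
                   method = "Nelder-Mead",
                   control = list(maxit = 5000, reltol = 1e-15)),
      error = function(e) NULL)
    if (!is.null(ob))
      cand[[length(cand) + 1L]] <- list(r = stats::plogis(ob$par[1]),
                                        a = exp(ob$par[-1]),
                                        ok = ob$convergence == 0)
  }
  ll <- vapply(cand, function(cc) ms_loglik(cc$r, cc$a, d, n, x), numeric(1))
  best <- cand[[which.max(ll)]]
  # snap negligible boundary coefficients to exactly zero when that does not
  # cost likelihood (within the convergence tolerance)
  a_snap <- ifelse(best$a < 1e-15, 0, best$a)
  if (ms_loglik(best$r, a_snap, d, n, x) >= max(ll) - 1e-10) best$a <- a_snap
  if (!is.finite(max(ll)))
    return(structure(new_fit(best$r, best$a, FALSE), class = "multistage"))
  # convergence check: a restart from the optimum must not improve the
  # log-likelihood beyond the tolerance
  chk <- tryCatch(stats::nlminb(
    c(best$r, best$a), function(p) -ms_loglik(p[1], p[-1], d, n, x),
    lower = lower, upper = upper,
    control = list(iter.max = 500, rel.tol = 1e-14)
  ), error = function(e) NULL)
  ok <- isTRUE(best$ok)
  if (!is.null(chk)) {
    if (-chk$objective > ms_loglik(best$r, best$a, d, n, x) + 1e-10) {
      best <- list(r = chk$par[1], a = pmax(chk$par[-1], 0))
      ok <- FALSE
    } else ok <- TRUE
  }
  fit <- new_fit(best$r, best$a, ok)
  if (!fit$converged)
    warning("multistage fit did not report convergence; inspect $converged",
            call. = FALSE)
  fit
}

#' Evaluate the multistage dose-response curve
#'
#' @param fit A \code{"multistage"} fit (from [fit_multistage()] or
#'   [benzene_cohort_lms()]).
#' @param dose Numeric vector of cumulative exposures (mg/m^3-year), >= 0.
#' @return Vector of response probabilities \eqn{P(d) \in [r, 1)}.
#' @examples
#' multistage_probability(benzene_cohort_lms(), c(0, 1.62, 86.79))
#' @export
multistage_probability <- function(fit, dose) {
  stopifnot(inherits(fit, "multistage"))
  if (any(!is.finite(dose)) || any(dose < 0))
    stop("dose must be finite and >= 0", call. = FALSE)
  ms_prob(fit$r, fit$a, dose)
}

#' Published multistage model for benzene-induced leukemia
#'
#' The degree-1 multistage model fitted to the Chinese benzene cohort, with
#' the coefficients frozen at their published 3-significant-figure values:
#' background \eqn{r = 4.32\times10^{-4}} and
#' \eqn{a_1 = 1.38\times10^{-6}} per mg/m^3-year. Use this object when
#' reproducing published risk tables; refit with [fit_multistage()] when you
#' want full-precision estimates.
#'
#' @return A \code{"multistage"} object (no attached data; \code{loglik} is
#'   \code{NA}).
#' @examples
#' round(1e4 * multistage_probability(benzene_cohort_lms(), 1.62), 2)
#' @export
benzene_cohort_lms <- function() {
  structure(list(
    r = 4.32e-4, a = c(a1 = 1.38e-6), degree = 1L,
    loglik = NA_real_, converged = TRUE, groups = NULL,
    df.residual = NA_integer_, call = quote(benzene_cohort_lms())
  ), class = "multistage")
}

#' Goodness of fit of a multistage model
#'
#' Compares observed and expected case counts per dose group with a
#' chi-square test on \code{df = groups - parameters} degrees of freedom.
#' Two statistics are available: the deviance (likelihood ratio against the
#' saturated model; the default) and the Pearson chi-square
#' \eqn{\sum_g (x_g - n_g p_g)^2 / (n_g p_g (1 - p_g))}. Both are reported;
#' \code{statistic} picks which one supplies the headline p-value.
#'
#' @param fit A converged \code{"multistage"} fit.
#' @param groups Dose groups to test against; defaults to the data the model
#'   was fitted to.
#' @param statistic \code{"deviance"} (default) or \code{"pearson"}.
#' @return A list of class \code{"multistage_gof"}: \code{chi_square},
#'   \code{df}, \code{p_value} for the chosen statistic, plus
#'   \code{pearson}, \code{deviance}, \code{p_pearson}, \code{p_deviance}.
#' @examples
#' goodness_of_fit(fit_multistage(chinese_benzene_cohort()))
#' @export
goodness_of_fit <- function(fit, groups = fit$groups,
                            statistic = c("deviance", "pearson")) {
  stopifnot(inherits(fit, "multistage"))
  statistic <- match.arg(statistic)
  if (is.null(groups)) stop("no dose groups supplied or stored in the fit",
                            call. = FALSE)
  if (!isTRUE(fit$converged))
    stop("goodness of fit requires a converged fit", call. = FALSE)
  groups <- as_dose_groups(groups)
  df <- nrow(groups) - (fit$degree + 1L)
  if (df <= 0L)
    stop("model is saturated (df <= 0); goodness-of-fit p undefined",
         call. = FALSE)
  d <- groups$dose_midpoint; n <- groups$n_subjects; x <- groups$n_cases
  p <- multistage_probability(fit, d)
  e <- n * p
  pearson <- sum((x - e)^2 / (e * (1 - p)))
  dev_term <- function(o, ee) ifelse(o == 0, 0, o * log(o / ee))
  deviance <- 2 * sum(dev_term(x, e) + dev_term(n - x, n - e))
  out <- list(
    statistic = statistic,
    pearson = pearson, deviance = deviance, df = df,
    p_pearson = stats::pchisq(pearson, df, lower.tail = FALSE),
    p_deviance = stats::pchisq(deviance, df, lower.tail = FALSE)
  )
  out$chi_square <- if (statistic == "pearson") pearson else deviance
  out$p_value <- if (statistic == "pearson") out$p_pearson else out$p_deviance
  class(out) <- "multistage_gof"
  out
}

#' @export
print.multistage_gof <- function(x, ...) {
  cat(sprintf("Goodness of fit (%s): chi-square = %.4f, df = %d, p = %.4f\n",
              x$statistic, x$chi_square, x$df, x$p_value))
  cat(sprintf("  [pearson %.4f (p = %.4f); deviance %.4f (p = %.4f)]\n",
              x$pearson, x$p_pearson, x$deviance, x$p_deviance))
  invisible(x)
}

#' Choose the multistage degree by goodness of fit
#'
#' Fits degrees \code{1..max_degree} (as far as identifiability allows a
#' goodness-of-fit test) and returns the fit whose GOF p-value is highest,
#' ties broken toward the lowest degree. The chosen fit carries its GOF
#' result as attribute \code{"gof"}.
#'
#' @inheritParams fit_multistage
#' @param max_degree Highest degree to consider (>= 1).
#' @param statistic Passed to [goodness_of_fit()].
#' @return The selected \code{"multistage"} fit.
#' @export
select_degree <- function(groups, max_degree = 2L,
                          statistic = c("deviance", "pearson")) {
  statistic <- match.arg(statistic)
  groups <- as_dose_groups(groups)
  if (max_degree < 1L) stop("max_degree must be >= 1", call. = FALSE)
  top <- min(as.integer(max_degree), nrow(groups) - 2L)  # keep df >= 1
  fits <- list(); ps <- numeric(0)
  for (k in seq_len(max(top, 0L))) {
    f <- tryCatch(fit_multistage(groups, degree = k), error = function(e) NULL)
    if (is.null(f) || !isTRUE(f$converged)) next
    g <- tryCatch(goodness_of_fit(f, statistic = statistic),
                  error = function(e) NULL)
    if (is.null(g)) next
    fits[[length(fits) + 1L]] <- structure(f, gof = g)
    ps <- c(ps, g$p_value)
  }
  if (!length(fits))
    stop("no candidate degree could be fitted and tested", call. = FALSE)
  fits[[which.max(ps)]]  # which.max returns the first (lowest-degree) tie
}

# ---- methods ---------------------------------------------------------------

#' @export
print.multistage <- function(x, digits = 4, ...) {
  cat("Multistage quantal dose-response model (degree ", x$degree, ")\n",
      sep = "")
  cat("  P(d) = r + (1 - r) * (1 - exp(-(",
      paste(sprintf("a%d*d^%d", seq_len(x$degree), seq_len(x$degree)),
            collapse = " + "), ")))\n", sep = "")
  print(signif(coef(x), digits))
  if (is.finite(x$loglik))
    cat("log-likelihood:", format(x$loglik, digits = digits + 2),
        " converged:", x$converged, "\n")
  invisible(x)
}

#' @export
coef.multistage <- function(object, ...) c(r = object$r, object$a)

#' @export
logLik.multistage <- function(object, ...) {
  structure(object$loglik, df = object$degree + 1L,
            nobs = if (!is.null(object$groups)) nrow(object$groups) else NA,
            class = "logLik")
}

#' Predict response probabilities from a multistage fit
#'
#' @param object A \code{"multistage"} fit.
#' @param dose Doses at which to evaluate; defaults to the fitted doses.
#' @param ... Unused.
#' @return Vector of probabilities.
#' @export
predict.multistage <- function(object, dose = NULL, ...) {
  if (is.null(dose)) {
    if (is.null(object$groups)) stop("supply 'dose': fit carries no data",
                                     call. = FALSE)
    dose <- object$groups$dose_midpoint
  }
  multistage_probability(object, dose)
}

#' @export
fitted.multistage <- function(object, ...) predict.multistage(object)

#' @export
residuals.multistage <- function(object, type = c("pearson", "deviance"), ...) {
  type <- match.arg(type)
  g <- object$groups
  if (is.null(g)) stop("fit carries no data", call. = FALSE)
  p <- predict.multistage(object)
  e <- g$n_subjects * p
  if (type == "pearson")
    return((g$n_cases - e) / sqrt(e * (1 - p)))
  term <- function(o, ee) ifelse(o == 0, 0, o * log(o / ee))
  sign(g$n_cases - e) *
    sqrt(pmax(2 * (term(g$n_cases, e) +
                   term(g$n_subjects - g$n_cases, g$n_subjects - e)), 0))
}

#' Simulate grouped case counts from a multistage fit
#'
#' Draws binomial case counts for each dose group of the fit (or of
#' \code{groups}) from the fitted response probabilities. Used for
#' parameter-recovery experiments.
#'
#' @param object A \code{"multistage"} fit.
#' @param nsim Number of replicate cohorts.
#' @param seed Optional integer seed.
#' @param groups Dose groups giving doses and subject counts; defaults to the
#'   fitted data.
#' @param ... Unused.
#' @return A data frame with one column per replicate (\code{sim_1}, ...) of
#'   simulated \code{n_cases}, with the dose groups as attribute
#'   \code{"groups"}.
#' @export
simulate.multistage <- function(object, nsim = 1, seed = NULL,
                                groups = object$groups, ...) {
  if (is.null(groups)) stop("fit carries no data; supply 'groups'",
                            call. = FALSE)
  groups <- as_dose_groups(groups)
  if (!is.null(seed)) set.seed(seed)
  p <- multistage_probability(object, groups$dose_midpoint)
  sims <- replicate(nsim, stats::rbinom(nrow(groups), groups$n_subjects, p))
  sims <- as.data.frame(matrix(sims, nrow = nrow(groups)))
  names(sims) <- paste0("sim_", seq_len(nsim))
  attr(sims, "groups") <- groups
  sims
}

#' Plot a multistage dose-response curve
#'
#' Draws the fitted curve over the observed dose range with the observed
#' group incidences overlaid.
#'
#' @param x A \code{"multistage"} fit.
#' @param dose_max Upper end of the dose axis; defaults to 1.1 times the
#'   largest fitted dose.
#' @param ... Passed to [graphics::plot()].
#' @return \code{x}, invisibly.
#' @export
plot.multistage <- function(x, dose_max = NULL, ...) {
  g <- x$groups
  if (is.null(dose_max))
    dose_max <- if (!is.null(g)) 1.1 * max(g$dose_midpoint) else 1
  dd <- seq(0, dose_max, length.out = 200)
  graphics::plot(dd, multistage_probability(x, dd), type = "l",
                 xlab = "cumulative exposure (mg/m³·year)",
                 ylab = "P(response)", ...)
  if (!is.null(g))
    graphics::points(g$dose_midpoint, g$n_cases / g$n_subjects, pch = 19)
  invisible(x)
}

#' @export
summary.multistage <- function(object, ...) {
  g <- object$groups
  tab <- NULL
  if (!is.null(g)) {
    p <- predict.multistage(object)
    tab <- data.frame(
      dose_midpoint = g$dose_midpoint, n_subjects = g$n_subjects,
      n_cases = g$n_cases, observed = g$n_cases / g$n_subjects,
      fitted = p, expected_cases = g$n_subjects * p
    )
  }
  gof <- if (!is.null(g) && isTRUE(object$converged) &&
             object$df.residual > 0)
    goodness_of_fit(object) else NULL
  structure(list(fit = object, table = tab, gof = gof),
            class = "summary.multistage")
}

#' @export
print.summary.multistage <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$table)) {
    cat("\nGroup table:\n")
    print(x$table, digits = 4, row.names = FALSE)
  }
  if (!is.null(x$gof)) { cat("\n"); print(x$gof) }
  invisible(x)
}
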