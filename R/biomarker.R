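#' Published metabolite-on-air regression coefficients
#'
#' The ln-ln multiple regressions of urinary benzene metabolites on airborne
#' benzene with a smoking dummy, frozen at their published values:
#' \describe{
#'   \item{S-PMA}{\eqn{\ln(\mathrm{SPMA}) = 0.77\,\ln C_{TWA} + 0.12\,SMO
#'     + 0.54}, \eqn{R^2 = 0.58}}
#'   \item{t,t-MA}{\eqn{\ln(\mathrm{ttMA}) = 0.68\,\ln C_{TWA} + 0.08\,SMO
#'     + 4.73}, \eqn{R^2 = 0.45}}
#' }
#' Metabolite concentrations are in ug/g creatinine, air benzene in mg/m^3,
#' SMO is 1 for smokers and 0 otherwise. Use these constants when
#' reproducing published biomarker-based risks; fit your own data with
#' [fit_loglog_regression()].
#'
#' @param metabolite \code{"spma"} or \code{"ttma"}.
#' @return A \code{"loglog_fit"} object (see [fit_loglog_regression()]);
#'   \code{residual_sd} is \code{NA} as it was not published.
#' @examples
#' invert_to_air(metabolite_coefs("ttma"), 5.18, smoker = 0)
#' @export
metabolite_coefs <- function(metabolite = c("spma", "ttma")) {
  metabolite <- match.arg(metabolite)
  cc <- switch(metabolite,
    spma = list(slope = 0.77, smoking = 0.12, intercept = 0.54,
                r_squared = 0.58),
    ttma = list(slope = 0.68, smoking = 0.08, intercept = 4.73,
                r_squared = 0.45)
  )
  structure(c(list(metabolite = metabolite), cc,
              list(residual_sd = NA_real_, n = 217L, model = NULL)),
            class = "loglog_fit")
}

#' Fit a ln-metabolite on ln-air regression with a smoking covariate
#'
#' Ordinary least squares of \code{ln(metabolite)} on \code{ln(C_TWA)} and
#' the smoking dummy, the calibration used to translate urinary metabolite
#' levels into equivalent airborne benzene concentrations.
#'
#' @param samples Data frame of per-sample measurements with columns
#'   \code{air_benzene_mg_m3} (> 0), \code{smoker} (0/1), and a metabolite
#'   column \code{spma_ug_gcr} or \code{ttma_ug_gcr} (> 0) matching
#'   \code{metabolite}.
#' @param metabolite \code{"spma"} or \code{"ttma"}.
#' @return A list of class \code{"loglog_fit"}: \code{metabolite},
#'   \code{slope} (on ln air), \code{smoking}, \code{intercept},
#'   \code{r_squared}, \code{residual_sd} (ln scale), \code{n} and the
#'   underlying \code{lm} object in \code{model}.
#' @seealso [predict_ln_metabolite()], [invert_to_air()],
#'   [risk_from_metabolite()]
#' @export
fit_loglog_regression <- function(samples, metabolite = c("spma", "ttma")) {
  metabolite <- match.arg(metabolite)
  mcol <- paste0(metabolite, "_ug_gcr")
  need <- c("air_benzene_mg_m3", "smoker", mcol)
  missing <- setdiff(need, names(samples))
  if (length(missing))
    stop("samples lack column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (nrow(samples) < 10L)
    stop("at least 10 samples are required", call. = FALSE)
  if (any(samples$air_benzene_mg_m3 <= 0) || any(samples[[mcol]] <= 0))
    stop("air and metabolite values must be > 0 for the log transform",
         call. = FALSE)
  dat <- data.frame(ln_met = log(samples[[mcol]]),
                    ln_air = log(samples$air_benzene_mg_m3),
                    smoker = as.numeric(samples$smoker))
  if (stats::var(dat$smoker) == 0 || stats::var(dat$ln_air) == 0)
    stop("rank-deficient design: a regressor is constant ",
         "(all smokers equal, or a single air level)", call. = FALSE)
  fit <- stats::lm(ln_met ~ ln_air + smoker, data = dat)
  if (anyNA(stats::coef(fit)))
    stop("rank-deficient design: coefficients not estimable", call. = FALSE)
  sm <- summary(fit)
  structure(list(
    metabolite = metabolite,
    slope = unname(stats::coef(fit)["ln_air"]),
    smoking = unname(stats::coef(fit)["smoker"]),
    intercept = unname(stats::coef(fit)["(Intercept)"]),
    r_squared = sm$r.squared,
    residual_sd = sm$sigma,
    n = nrow(dat),
    model = fit
  ), class = "loglog_fit")
}

#' @export
print.loglog_fit <- function(x, ...) {
  cat(sprintf(
    "ln(%s) = %.4f ln(C_TWA) + %.4f SMO + %.4f   (R^2 = %.3f, n = %d)\n",
    x$metabolite, x$slope, x$smoking, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Predict the ln metabolite concentration at a given air level
#'
#' @param fit A \code{"loglog_fit"}.
#' @param c_twa Airborne benzene, mg/m^3 (> 0).
#' @param smoker Smoking dummy, 0 or 1.
#' @return \code{slope * ln(c_twa) + smoking * smoker + intercept}, in
#'   ln(ug/g creatinine).
#' @export
predict_ln_metabolite <- function(fit, c_twa, smoker = 0) {
  stopifnot(inherits(fit, "loglog_fit"))
  if (any(c_twa <= 0)) stop("c_twa must be > 0", call. = FALSE)
  if (!all(smoker %in% c(0, 1))) stop("smoker must be 0 or 1", call. = FALSE)
  fit$slope * log(c_twa) + fit$smoking * smoker + fit$intercept
}

#' Invert a metabolite measurement to an airborne concentration
#'
#' Solves the ln-ln regression for \eqn{C_{TWA}}:
#' \eqn{\exp[(\ln m - s\,SMO - c)/b]}. Round-trips
#' [predict_ln_metabolite()] exactly.
#'
#' @param fit A \code{"loglog_fit"}.
#' @param value Metabolite concentration, ug/g creatinine (> 0).
#' @param smoker Smoking dummy, 0 or 1.
#' @return Equivalent airborne benzene concentration, mg/m^3.
#' @examples
#' invert_to_air(metabolite_coefs("ttma"), 5.18, smoker = 0)
#' @export
invert_to_air <- function(fit, value, smoker = 0) {
  stopifnot(inherits(fit, "loglog_fit"))
  if (any(value <= 0)) stop("metabolite value must be > 0", call. = FALSE)
  if (!all(smoker %in% c(0, 1))) stop("smoker must be 0 or 1", call. = FALSE)
  if (fit$slope == 0) stop("zero slope: regression cannot be inverted",
                           call. = FALSE)
  exp((log(value) - fit$smoking * smoker - fit$intercept) / fit$slope)
}

#' Leukemia risk from a urinary metabolite measurement
#'
#' Chains the inverted metabolite regression into the multistage model: the
#' measurement is translated to an equivalent airborne concentration, turned
#' into a cumulative exposure with the working duration, and evaluated under
#' the dose-response model.
#'
#' @param lms A \code{"multistage"} fit (e.g. [benzene_cohort_lms()]).
#' @param fit A \code{"loglog_fit"} for the measured metabolite.
#' @param value Metabolite concentration, ug/g creatinine (> 0).
#' @param smoker Smoking dummy, 0 or 1.
#' @param t Working duration, years (>= 0).
#' @return Risk probability.
#' @examples
#' # below-LOD workers assessed from their median t,t-MA
#' risk_from_metabolite(benzene_cohort_lms(), metabolite_coefs("ttma"),
#'                      value = 5.18, smoker = 0, t = 1.78)
#' @export
risk_from_metabolite <- function(lms, fit, value, smoker = 0, t = 1) {
  risk_from_twa(lms, invert_to_air(fit, value, smoker), t)
}
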