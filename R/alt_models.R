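# EPA inhalation-unit-risk model and the Singapore semi-quantitative
# occupational health risk matrix, used to cross-validate the multistage
# risk estimates.

#' Default EPA exposure parameters
#'
#' Occupational defaults for the EPA inhalation risk model: an 8 h/d
#' monitored shift, 250 working days per year, the 2020 Chinese life
#' expectancy of 77.93 years as averaging time, and the IRIS inhalation unit
#' risk range for benzene-induced leukemia, (2.2-7.8) x 10^-6 per ug/m^3.
#'
#' @return Named list: \code{et_h_per_day}, \code{ef_days_per_year},
#'   \code{life_expectancy_years}, \code{iur_low}, \code{iur_high}.
#' @export
epa_defaults <- function() {
  list(et_h_per_day = 8, ef_days_per_year = 250,
       life_expectancy_years = 77.93,
       iur_low = 2.2e-6, iur_high = 7.8e-6)
}

#' Lifetime-averaged exposure concentration
#'
#' \eqn{EC = CA \times ET \times EF \times ED / AT}: the workplace
#' concentration averaged over a lifetime of \code{at_hours} hours.
#'
#' @param ca Workplace air concentration, ug/m^3 (>= 0).
#' @param et Exposure hours per day.
#' @param ef Exposure days per year.
#' @param ed Exposure duration, years.
#' @param at Averaging time, hours (> 0); typically life expectancy in years
#'   times 365 x 24.
#' @return Exposure concentration in ug/m^3; never exceeds \code{ca}.
#' @export
exposure_concentration <- function(ca, et, ef, ed, at) {
  if (any(ca < 0)) stop("ca must be >= 0", call. = FALSE)
  if (any(c(et, ef, ed) <= 0)) stop("et, ef and ed must be > 0", call. = FALSE)
  if (any(at <= 0)) stop("averaging time must be > 0", call. = FALSE)
  if (any(et * ef * ed > at + 1e-9))
    stop("exposure hours exceed the averaging time", call. = FALSE)
  ca * et * ef * ed / at
}

#' EPA inhalation cancer risk
#'
#' \eqn{Risk = IUR \times EC}.
#'
#' @param ec Exposure concentration, ug/m^3 (>= 0).
#' @param iur Inhalation unit risk, per ug/m^3 (>= 0). Vectorized, so both
#'   IUR bounds can be passed at once.
#' @return Risk probability (product).
#' @export
epa_risk <- function(ec, iur) {
  if (any(ec < 0) || any(iur < 0)) stop("ec and iur must be >= 0",
                                        call. = FALSE)
  ec * iur
}

#' EPA risk range for an exposure group
#'
#' Convenience adapter: converts a group's mean airborne benzene from
#' mg/m^3 to ug/m^3, computes the lifetime-averaged exposure concentration
#' with the group's mean working duration as ED, and returns the risk at
#' both IUR bounds.
#'
#' @param c_twa_mg_m3 Group mean airborne concentration, mg/m^3.
#' @param ed_years Group mean working duration, years.
#' @param config Parameter list as from [epa_defaults()].
#' @return Data frame with \code{ec_ug_m3}, \code{risk_low}, \code{risk_high}.
#' @examples
#' epa_group_risk(2.31, 0.76)
#' @export
epa_group_risk <- function(c_twa_mg_m3, ed_years, config = epa_defaults()) {
  at <- config$life_expectancy_years * 365 * 24
  ec <- exposure_concentration(c_twa_mg_m3 * 1000, config$et_h_per_day,
                               config$ef_days_per_year, ed_years, at)
  data.frame(ec_ug_m3 = ec,
             risk_low = epa_risk(ec, config$iur_low),
             risk_high = epa_risk(ec, config$iur_high))
}

#' Singapore exposure rating
#'
#' Bins the ratio of the exposure dose to the occupational exposure limit
#' into the 1-5 exposure rating: ER = 1 for E/OEL < 0.1, 2 for [0.1, 0.5),
#' 3 for [0.5, 1), 4 for [1, 2) and 5 for E/OEL >= 2.
#'
#' @param e Exposure dose, mg/m^3 (>= 0).
#' @param oel Occupational exposure limit, mg/m^3 (> 0); 3 mg/m^3 for
#'   benzene in China.
#' @return Integer rating(s) in 1..5.
#' @export
exposure_rating <- function(e, oel = 3) {
  if (any(oel <= 0)) stop("oel must be > 0", call. = FALSE)
  if (any(e < 0)) stop("exposure must be >= 0", call. = FALSE)
  ratio <- e / oel
  as.integer(cut(ratio, breaks = c(-Inf, 0.1, 0.5, 1, 2, Inf),
                 labels = FALSE, right = FALSE))
}

singapore_labels <- c("Negligible risk", "Low risk", "Medium risk",
                      "High risk", "Very high risk")

#' Singapore semi-quantitative risk rating
#'
#' Combines a hazard rating and an exposure rating into the semi-quantitative
#' risk value \eqn{\sqrt{HR \times ER}} (so the value stays on the 1-5
#' scale), the nearest-integer risk grade, and its label. The raw product
#' \eqn{HR \times ER} is also returned.
#'
#' @param hr Hazard rating, integer 1-5 (5 for a confirmed human carcinogen
#'   such as benzene).
#' @param er Exposure rating, integer 1-5 (see [exposure_rating()]).
#' @return List of class \code{"singapore_rating"}: \code{hr}, \code{er},
#'   \code{risk_value}, \code{product}, \code{risk_grade}, \code{label}.
#' @examples
#' singapore_risk(hr = 5, er = 3)
#' @export
singapore_risk <- function(hr, er) {
  if (!all(hr %in% 1:5) || !all(er %in% 1:5))
    stop("hr and er must be integers in 1..5", call. = FALSE)
  value <- sqrt(hr * er)
  grade <- as.integer(round(value))
  structure(list(hr = hr, er = er, risk_value = value, product = hr * er,
                 risk_grade = grade, label = singapore_labels[grade]),
            class = "singapore_rating")
}

#' @export
print.singapore_rating <- function(x, ...) {
  cat(sprintf("HR %d x ER %d -> risk value %.2f, grade %d (%s)\n",
              x$hr, x$er, x$risk_value, x$risk_grade, x$label))
  invisible(x)
}

#' Singapore rating from an exposure level
#'
#' @param e Exposure dose (group mean C_TWA), mg/m^3.
#' @param oel Occupational exposure limit, mg/m^3.
#' @param hr Hazard rating (default 5, carcinogen).
#' @return A [singapore_risk()] rating.
#' @examples
#' singapore_from_exposure(2.31, oel = 3)
#' @export
singapore_from_exposure <- function(e, oel = 3, hr = 5) {
  singapore_risk(hr, exposure_rating(e, oel))
}
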