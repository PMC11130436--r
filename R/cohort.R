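#' Grouped cohort dose-response data
#'
#' Construct a validated table of dose groups for quantal dose-response
#' modelling. Each row is one exposure stratum of a cohort: the midpoint of
#' its cumulative benzene exposure interval, the number of subjects, and the
#' number of leukemia cases observed among them.
#'
#' @param dose_midpoint Numeric vector of cumulative exposure midpoints, in
#'   mg/m^3-year. Must be non-negative.
#' @param n_subjects Integer vector of subjects per group (> 0).
#' @param n_cases Integer vector of cases per group, \code{0 <= n_cases <=
#'   n_subjects}.
#' @return A \code{data.frame} of class \code{"dose_groups"} with the three
#'   columns above, ordered by increasing dose.
#' @seealso [chinese_benzene_cohort()] for the bundled cohort table,
#'   [fit_multistage()] to fit a model to it.
#' @examples
#' dose_groups(c(0, 65, 388), c(35804, 31923, 24605), c(18, 13, 25))
#' @export
dose_groups <- function(dose_midpoint, n_subjects, n_cases) {
  g <- data.frame(
    dose_midpoint = as.numeric(dose_midpoint),
    n_subjects = as.numeric(n_subjects),
    n_cases = as.numeric(n_cases)
  )
  validate_dose_groups(g)
  g <- g[order(g$dose_midpoint), , drop = FALSE]
  rownames(g) <- NULL
  class(g) <- c("dose_groups", "data.frame")
  g
}

validate_dose_groups <- function(g) {
  if (!all(c("dose_midpoint", "n_subjects", "n_cases") %in% names(g)))
    stop("dose groups need columns dose_midpoint, n_subjects, n_cases",
         call. = FALSE)
  if (anyNA(g)) stop("dose groups contain missing values", call. = FALSE)
  if (any(g$dose_midpoint < 0)) stop("dose_midpoint must be >= 0", call. = FALSE)
  if (any(g$n_subjects <= 0)) stop("n_subjects must be > 0", call. = FALSE)
  if (any(g$n_cases < 0 | g$n_cases > g$n_subjects))
    stop("n_cases must satisfy 0 <= n_cases <= n_subjects", call. = FALSE)
  if (anyDuplicated(g$dose_midpoint))
    stop("duplicated dose_midpoint; pool groups at the same dose", call. = FALSE)
  invisible(g)
}

as_dose_groups <- function(x) {
  if (inherits(x, "dose_groups")) return(x)
  if (is.data.frame(x))
    return(dose_groups(x$dose_midpoint, x$n_subjects, x$n_cases))
  stop("cannot interpret input as dose groups", call. = FALSE)
}

#' Read dose groups from CSV
#'
#' Reads a grouped-cohort file with header
#' \code{dose_midpoint,n_subjects,n_cases} and validates it.
#'
#' @param path Path to a CSV file.
#' @return A [dose_groups()] table.
#' @export
read_dose_groups <- function(path) {
  g <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop("failed to parse '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  missing <- setdiff(c("dose_midpoint", "n_subjects", "n_cases"), names(g))
  if (length(missing))
    stop("'", path, "' lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  dose_groups(g$dose_midpoint, g$n_subjects, g$n_cases)
}

#' Chinese benzene cohort incidence table
#'
#' The grouped leukemia incidence data of the Chinese benzene cohort
#' (35,804 unexposed and 56,528 exposed workers followed 1972-1987),
#' stratified by cumulative benzene exposure: midpoints 0, 65 and 388
#' mg/m^3-year with 18, 13 and 25 leukemia cases. This is the dataset the
#' bundled multistage model [benzene_cohort_lms()] was fitted to.
#'
#' @return A [dose_groups()] table with three rows.
#' @examples
#' summarize_cohort(chinese_benzene_cohort())
#' @export
chinese_benzene_cohort <- function() {
  path <- system.file("extdata", "chinese_benzene_cohort.csv",
                      package = "benzrisk", mustWork = TRUE)
  read_dose_groups(path)
}

#' Per-group incidence and relative risk
#'
#' Crude incidence (cases / subjects) for every dose group and the relative
#' risk of each group against the zero-dose (unexposed) reference stratum.
#'
#' @param groups A [dose_groups()] table (or coercible data frame) that
#'   contains a group with \code{dose_midpoint == 0}.
#' @return A data frame with columns \code{dose_midpoint}, \code{n_subjects},
#'   \code{n_cases}, \code{incidence} and \code{rr}. The reference group has
#'   \code{rr = 1} by convention (also when its incidence is zero).
#' @examples
#' summarize_cohort(chinese_benzene_cohort())
#' @export
summarize_cohort <- function(groups) {
  groups <- as_dose_groups(groups)
  i0 <- which(groups$dose_midpoint == 0)
  if (length(i0) != 1L)
    stop("a single zero-dose reference group is required to compute RR",
         call. = FALSE)
  out <- as.data.frame(groups)
  out$incidence <- out$n_cases / out$n_subjects
  ref <- out$incidence[i0]
  out$rr <- if (ref > 0) out$incidence / ref else ifelse(out$incidence > 0, Inf, NaN)
  out$rr[i0] <- 1
  out
}
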