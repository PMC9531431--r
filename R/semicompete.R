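#' Competing-risks endpoint for QOL deterioration
#'
#' Derives, per patient, the first-event record for the semi-competing
#' setting with QOL deterioration as the event of interest and death
#' without prior deterioration as the competing event (a death after an
#' observed deterioration is irrelevant: the event of interest has
#' already occurred; a death without deterioration removes the
#' possibility of the event, i.e. postpones it beyond any horizon).
#'
#' @param trial A `trial_data` object.
#' @param threshold Deterioration threshold in points (default 10).
#' @return Tibble `patient_id`, `arm`, `time`, `cause`
#'   (`"deterioration"`, `"death"`, `"censored"`).
#' @export
competing_endpoint <- function(trial, threshold = 10) {
  ttd_endpoint(trial, threshold = threshold) |>
    dplyr::mutate(cause = ifelse(.data$cause == "none", "censored",
                                 .data$cause)) |>
    dplyr::select("patient_id", "arm", "time", "cause")
}

#' Aalen-Johansen cumulative incidence curves
#'
#' Nonparametric cumulative incidence functions (crude risk) of the two
#' competing causes, \eqn{CIF_k(t) = \sum_{u \le t} S(u-) d_k(u)/n(u)}
#' with `S` the all-cause product-limit estimate, computed with the
#' multi-state Aalen-Johansen estimator. At every time the two CIFs and
#' the event-free probability sum to one.
#'
#' @param records Tibble from [competing_endpoint()] (columns `time`,
#'   `cause`), typically one arm.
#' @param arm_label Optional label stored with the curve.
#' @return An object of class `cif_curve`: list with `curve` (tibble
#'   `time`, `cif_deterioration`, `cif_death`, `event_free`, `at_risk`,
#'   including the origin), `n` and `arm_label`.
#' @export
cif_estimate <- function(records, arm_label = NULL) {
  stopifnot(nrow(records) > 0)
  cause <- factor(records$cause,
                  levels = c("censored", "deterioration", "death"))
  fit <- survival::survfit(survival::Surv(records$time, cause) ~ 1)
  states <- fit$states
  ps <- fit$pstate
  if (is.null(dim(ps))) ps <- matrix(ps, nrow = 1, dimnames = list(NULL, states))
  nr <- fit$n.risk
  if (is.null(dim(nr))) nr <- matrix(nr, nrow = 1)
  i_det <- which(states == "deterioration")
  i_death <- which(states == "death")
  i_free <- which(states == "(s0)")
  curve <- tibble::tibble(
    time = c(0, fit$time),
    cif_deterioration = unname(c(0, ps[, i_det])),
    cif_death = unname(c(0, ps[, i_death])),
    event_free = unname(c(1, ps[, i_free])),
    at_risk = unname(c(fit$n, nr[, 1]))
  )
  structure(list(curve = curve, n = nrow(records), arm_label = arm_label),
            class = "cif_curve")
}

#' @export
print.cif_curve <- function(x, ...) {
  last <- x$curve[nrow(x$curve), ]
  cat("<cif_curve>", if (!is.null(x$arm_label)) paste0("arm ", x$arm_label),
      sprintf("n = %d, final CIF(det) = %.3f, CIF(death) = %.3f\n",
              x$n, last$cif_deterioration, last$cif_death))
  invisible(x)
}

#' Gray's test comparing cumulative incidence between arms
#'
#' Gray's sub-distribution score test (rho = 0) of equality of the
#' cumulative incidence functions of the cause of interest.
#'
#' @param records Tibble with `time`, `cause`, `arm` (both arms).
#' @param cause_of_interest Default `"deterioration"`.
#' @return One-row tibble: `statistic` (chi-square), `df`, `p_value`.
#' @export
gray_test <- function(records, cause_of_interest = "deterioration") {
  stopifnot(length(unique(records$arm)) == 2)
  if (!any(records$cause == cause_of_interest)) {
    stop("no events of the cause of interest", call. = FALSE)
  }
  fit <- cmprsk::cuminc(ftime = records$time, fstatus = records$cause,
                        group = records$arm, cencode = "censored")
  tests <- fit$Tests
  row <- which(rownames(tests) == cause_of_interest)
  tibble::tibble(
    statistic = unname(tests[row, "stat"]),
    df = unname(tests[row, "df"]),
    p_value = unname(tests[row, "pv"])
  )
}

#' Fine-Gray sub-distribution hazard ratio
#'
#' Weighted partial-likelihood estimate of the new-vs-standard
#' sub-distribution hazard ratio for the cause of interest. Censoring
#' weights come from the product-limit estimate of the censoring
#' distribution pooled over arms (the `finegray` expansion), and the
#' weighted Cox fit reports a robust standard error.
#'
#' @param records Tibble with `time`, `cause`, `arm` (both arms).
#' @param cause_of_interest Default `"deterioration"`.
#' @return One-row tibble: `loghr`, `se` (robust), `hr`, `ci_lo`,
#'   `ci_hi`, `n_events`.
#' @export
fine_gray_hr <- function(records, cause_of_interest = "deterioration") {
  stopifnot(length(unique(records$arm)) == 2)
  if (!any(records$cause == cause_of_interest)) {
    stop("no events of the cause of interest", call. = FALSE)
  }
  df <- data.frame(
    time = records$time,
    cause = factor(records$cause,
                   levels = c("censored",
                              setdiff(unique(records$cause), "censored"))),
    arm = records$arm
  )
  fg <- survival::finegray(survival::Surv(time, cause) ~ arm, data = df,
                           etype = cause_of_interest)
  fit <- survival::coxph(
    survival::Surv(fgstart, fgstop, fgstatus) ~ arm,
    weights = fg$fgwt, data = fg
  )
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))   # robust (weighted fit)
  tibble::tibble(
    loghr = beta, se = se, hr = exp(beta),
    ci_lo = exp(beta - 1.96 * se), ci_hi = exp(beta + 1.96 * se),
    n_events = sum(records$cause == cause_of_interest)
  )
}
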