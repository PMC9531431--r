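#' First QOL deterioration time
#'
#' The first visit month at which QOL has declined from baseline by at
#' least `threshold` points. The month-0 measurement is the baseline
#' reference; a decline of exactly `threshold` counts. A single
#' deterioration suffices (no confirmation at a later visit is required)
#' and the event is dated at the visit where it is first observed.
#'
#' @param baseline_qol Baseline (month-0) QOL value.
#' @param visit_month,value Time-ordered QOL series of one patient.
#' @param threshold Points of decline defining deterioration (default 10).
#' @return The deterioration month, or `NA` if never observed.
#' @export
#' @examples
#' deterioration_time(80, c(3, 6), c(75, 69))  # 6
deterioration_time <- function(baseline_qol, visit_month, value, threshold = 10) {
  if (length(value) == 0 || is.na(baseline_qol)) return(NA_real_)
  hit <- which(baseline_qol - value >= threshold)
  if (length(hit) == 0) NA_real_ else visit_month[hit[1]]
}

#' Time-to-deterioration composite endpoint
#'
#' Derives, per patient, the time to the first of death or QOL
#' deterioration (>= `threshold` points below baseline); patients with
#' neither are censored at their follow-up time.
#'
#' @param trial A `trial_data` object.
#' @param threshold Deterioration threshold in points (default 10).
#' @return A tibble with `patient_id`, `arm`, `time`, `event`
#'   (`"event"`/`"censored"`) and `cause`
#'   (`"deterioration"`, `"death"`, `"none"`).
#' @export
ttd_endpoint <- function(trial, threshold = 10) {
  det <- trial$qol |>
    dplyr::inner_join(trial$patients[, c("patient_id", "baseline_qol")],
                      by = "patient_id") |>
    dplyr::arrange(.data$patient_id, .data$visit_month) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(det_time = deterioration_time(
      .data$baseline_qol[1], .data$visit_month, .data$value, threshold
    ))
  trial$patients |>
    dplyr::left_join(det, by = "patient_id") |>
    dplyr::mutate(
      time = pmin(.data$det_time, .data$death_time, na.rm = TRUE),
      time = ifelse(is.na(.data$time), .data$followup_time, .data$time),
      cause = dplyr::case_when(
        !is.na(.data$det_time) &
          (is.na(.data$death_time) | .data$det_time <= .data$death_time) ~
          "deterioration",
        !is.na(.data$death_time) ~ "death",
        .default = "none"
      ),
      event = ifelse(.data$cause == "none", "censored", "event")
    ) |>
    dplyr::select("patient_id", "arm", "time", "event", "cause")
}

#' Kaplan-Meier step curve
#'
#' Product-limit estimate of the survival (event-free) function with
#' censoring, plus the median event time (smallest time at which the
#' estimate drops to 0.5 or below) and a lookup of the estimate at any
#' time.
#'
#' @param time Event/censoring times in months.
#' @param event Logical or 0/1 event indicator (1 = event).
#' @param arm_label Optional label stored with the curve.
#' @return An object of class `step_curve`: list with `curve` (tibble
#'   `time`, `estimate`, `at_risk`, including the origin at time 0),
#'   `median` (`NA` with `median_estimable = FALSE` when the curve never
#'   reaches 0.5), `n`, `n_events` and `arm_label`.
#' @export
#' @examples
#' km <- km_estimate(c(2, 4, 6), c(1, 1, 1))
#' km$curve
km_estimate <- function(time, event, arm_label = NULL) {
  stopifnot(length(time) > 0, all(time >= 0))
  event <- as.integer(as.logical(event))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  curve <- tibble::tibble(
    time = c(0, fit$time),
    estimate = c(1, fit$surv),
    at_risk = c(fit$n, fit$n.risk)
  )
  below <- which(curve$estimate <= 0.5)
  med <- if (length(below) == 0) NA_real_ else curve$time[below[1]]
  structure(
    list(curve = curve, median = med,
         median_estimable = length(below) > 0,
         n = length(time), n_events = sum(event), arm_label = arm_label),
    class = "step_curve"
  )
}

#' @export
print.step_curve <- function(x, ...) {
  cat("<step_curve>", if (!is.null(x$arm_label)) paste0("arm ", x$arm_label),
      sprintf("n = %d, events = %d, median = %s\n", x$n, x$n_events,
              if (x$median_estimable) format(x$median) else "not estimable"))
  invisible(x)
}

#' Survival estimate at a given time
#'
#' @param km A [km_estimate()] object.
#' @param at Time in months (vectorized).
#' @return The right-continuous step-function value(s).
#' @export
km_surv_at <- function(km, at) {
  stopifnot(inherits(km, "step_curve"))
  idx <- findInterval(at, km$curve$time)
  km$curve$estimate[pmax(idx, 1)]
}

#' Cox proportional-hazards arm effect
#'
#' Fits the maximum-partial-likelihood hazard ratio of the binary arm
#' covariate. With `cause_filter` set, competing causes are treated as
#' censoring, yielding the cause-specific hazard ratio.
#'
#' @param records Tibble with `time`, `event` (`"event"`/`"censored"` or
#'   0/1), `arm`, and (when `cause_filter` is used) `cause`.
#' @param cause_filter Optional cause value(s) counted as events.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return One-row tibble: `loghr`, `se`, `hr`, `ci_lo`, `ci_hi`,
#'   `n_events`, `monotone_likelihood` flag.
#' @export
cox_hr <- function(records, cause_filter = NULL, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  status <- if (is.character(records$event)) {
    as.integer(records$event == "event" | records$event == "death")
  } else {
    as.integer(records$event)
  }
  if (!is.null(cause_filter)) {
    status <- as.integer(status == 1L & records$cause %in% cause_filter)
  }
  if (length(unique(records$arm)) < 2) {
    stop("both arms must be represented", call. = FALSE)
  }
  if (sum(status) == 0) stop("no events; hazard ratio not estimable", call. = FALSE)
  fit <- survival::coxph(survival::Surv(records$time, status) ~ records$arm,
                         ties = ties)
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  tibble::tibble(
    loghr = beta, se = se, hr = exp(beta),
    ci_lo = exp(beta - 1.96 * se), ci_hi = exp(beta + 1.96 * se),
    n_events = sum(status),
    monotone_likelihood = !is.finite(beta) || abs(beta) > 15
  )
}

#' Overall-survival records of a trial
#'
#' @param trial A `trial_data` object.
#' @return Tibble `patient_id`, `arm`, `time` (follow-up), `event`
#'   (1 = death) suitable for [km_estimate()] and [cox_hr()].
#' @export
os_records <- function(trial) {
  tibble::tibble(
    patient_id = trial$patients$patient_id,
    arm = trial$patients$arm,
    time = trial$patients$followup_time,
    event = as.integer(trial$patients$event == "death")
  )
}
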