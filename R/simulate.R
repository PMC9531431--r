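#' Inverse-CDF survival draw with a no-death plateau
#'
#' Transforms uniform draws into overall-survival times from an
#' exponential law with the given hazard, then shifts any draw exceeding
#' the plateau start by the plateau width, so that no returned time falls
#' in the half-open interval `(plateau[1], plateau[2]]`. The shift leaves
#' the survival function unchanged up to the plateau start (in particular
#' S(12) = 0.5 at the default rate) and preserves a constant hazard ratio
#' between arms wherever the hazard is nonzero.
#'
#' @param u Uniform(0,1) draws (vectorized).
#' @param rate Hazard per month (> 0).
#' @param plateau No-death interval, default `c(12, 18)`.
#' @return Survival times in months, same length as `u`.
#' @export
#' @examples
#' draw_survival(0.5, log(2) / 12) # exactly 12 months
draw_survival <- function(u, rate, plateau = c(12, 18)) {
  if (length(rate) != 1 || !is.finite(rate) || rate <= 0) {
    stop("`rate` must be a single positive number", call. = FALSE)
  }
  if (any(u <= 0 | u >= 1)) stop("`u` must lie strictly in (0, 1)", call. = FALSE)
  t_star <- -log(u) / rate
  ifelse(t_star <= plateau[1], t_star, t_star + (plateau[2] - plateau[1]))
}

#' Latent QOL value with terminal decline
#'
#' The noise-free QOL trajectory: flat at `stable_level` until
#' `window` months before death, then declining linearly so that the
#' value at the moment of death is `stable_level - depth`. Values are
#' clipped to the 0-100 instrument range.
#'
#' @param stable_level Stable QOL level (points).
#' @param death_time Death time in months.
#' @param visit Visit month; must not exceed `death_time`.
#' @param depth Total decline depth D at death (points).
#' @param window Decline window \eqn{\delta} in months before death
#'   (default 6).
#' @return QOL points in `[0, 100]` (vectorized over the arguments).
#' @export
#' @examples
#' latent_qol(80, death_time = 15, visit = 6)  # stable: 9 months from death
#' latent_qol(80, death_time = 6, visit = 6)   # at death: 80 - 20
latent_qol <- function(stable_level, death_time, visit, depth = 20, window = 6) {
  if (any(window <= 0)) stop("`window` must be > 0", call. = FALSE)
  gap <- death_time - visit
  if (any(gap < -1e-12)) stop("`visit` must not exceed `death_time`", call. = FALSE)
  val <- ifelse(gap >= window,
                stable_level,
                stable_level - depth * (window - gap) / window)
  pmin(pmax(val, 0), 100)
}

#' Simulate one two-arm trial with QOL truncated by death
#'
#' Generates patient-level survival and long-format QOL data together with
#' the latent potential outcomes that define the ground truth for the
#' survivor average causal effect (SACE).
#'
#' One shared uniform draw per patient produces the potential death times
#' under both arms via [draw_survival()] at the standard and
#' hazard-ratio-scaled rates (common random numbers, hence rank-preserving
#' potential outcomes: T(1) >= T(0) exactly when the hazard ratio is <= 1).
#' The observed death time is the potential time under the assigned arm;
#' follow-up is its minimum with an independent exponential censoring
#' time. QOL is recorded at every scheduled visit up to follow-up as the
#' latent trajectory value plus Gaussian measurement noise, clipped to
#' `[0, 100]`; no measurement exists after death or censoring. Each
#' patient's stable level is `stable_mean + sex_effect * sex` plus a
#' between-patient Gaussian deviate.
#'
#' Potential QOL values are noise-free. When `qol_effect_on` is `TRUE`
#' the trajectory under each arm is anchored to that arm's potential
#' death time with the arm's decline depth. When it is `FALSE` (no
#' treatment effect on the QOL process, scenario 4) both potential
#' trajectories are identical by construction: they follow the control-arm
#' death process, so the true SACE contrast is exactly zero at every
#' visit, while *observed* QOL still declines before the assigned arm's
#' actual death.
#'
#' @param config A [trial_config()].
#' @return A list of class `trial_data` with elements
#' \describe{
#'   \item{patients}{tibble: `patient_id`, `arm` (0 standard / 1 new),
#'     `sex`, `baseline_qol` (the measured month-0 value),
#'     `followup_time`, `event` ("death"/"censored"), `death_time`
#'     (`NA` when censored first).}
#'   \item{qol}{tibble: `patient_id`, `visit_month`, `value`.}
#'   \item{potential}{tibble of latent truth: `patient_id`,
#'     `death_time_standard`, `death_time_new`, and per scheduled visit
#'     `visit_month`, `qol_standard`, `qol_new` (`NA` after the relevant
#'     potential death).}
#'   \item{config}{the configuration, echoed.}
#' }
#' @export
#' @examples
#' trial <- simulate_trial(trial_config(scenario = 1, n_patients = 200, seed = 7))
#' head(trial$patients)
simulate_trial <- function(config) {
  stopifnot(inherits(config, "trial_config"))
  n <- config$n_patients
  qp <- config$qol_params
  sched <- config$qol_schedule
  k <- length(sched)

  set.seed(config$seed)
  # fixed draw order => common random numbers across scenarios sharing a seed
  arm <- stats::rbinom(n, 1L, 0.5)
  sex <- stats::rbinom(n, 1L, 0.5)
  stable_dev <- stats::rnorm(n, 0, qp$stable_sd)
  u_surv <- stats::runif(n)
  u_cens <- stats::runif(n)
  noise <- matrix(stats::rnorm(n * k, 0, qp$noise_sd), nrow = n, ncol = k)

  r0 <- config$standard_rate
  t0 <- draw_survival(u_surv, r0, config$plateau)
  t1 <- draw_survival(u_surv, r0 * config$hazard_ratio, config$plateau)
  t_obs <- ifelse(arm == 1L, t1, t0)

  cens <- -log(u_cens) / config$censor_rate
  followup <- pmin(t_obs, cens)
  event <- ifelse(t_obs <= cens, "death", "censored")
  death_time <- ifelse(event == "death", t_obs, NA_real_)

  stable <- qp$stable_mean + qp$sex_effect * sex + stable_dev
  depth_obs <- ifelse(arm == 1L, qp$decline_depth_new, qp$decline_depth_standard)

  # observed QOL: visits up to follow-up, latent value + noise, clipped
  visit_mat <- matrix(sched, nrow = n, ncol = k, byrow = TRUE)
  on_study <- visit_mat <= followup
  idx <- which(on_study, arr.ind = TRUE)
  v <- sched[idx[, 2]]
  i <- idx[, 1]
  qol_val <- latent_qol(stable[i], t_obs[i], v, depth_obs[i], qp$decline_window)
  qol_val <- pmin(pmax(qol_val + noise[idx], 0), 100)
  qol <- tibble::tibble(patient_id = i, visit_month = v, value = qol_val)
  qol <- dplyr::arrange(qol, .data$patient_id, .data$visit_month)

  baseline <- rep(NA_real_, n)
  b0 <- qol$visit_month == 0
  baseline[qol$patient_id[b0]] <- qol$value[b0]

  patients <- tibble::tibble(
    patient_id = seq_len(n), arm = arm, sex = sex,
    baseline_qol = baseline, followup_time = followup,
    event = event, death_time = death_time
  )

  # latent potential QOL (noise-free)
  grid <- tidyr::expand_grid(patient_id = seq_len(n), visit_month = sched)
  gi <- grid$patient_id
  gm <- grid$visit_month
  if (config$qol_effect_on) {
    q0 <- ifelse(gm <= t0[gi],
                 latent_qol(stable[gi], t0[gi], pmin(gm, t0[gi]),
                            qp$decline_depth_standard, qp$decline_window),
                 NA_real_)
    q1 <- ifelse(gm <= t1[gi],
                 latent_qol(stable[gi], t1[gi], pmin(gm, t1[gi]),
                            qp$decline_depth_new, qp$decline_window),
                 NA_real_)
  } else {
    q0 <- ifelse(gm <= t0[gi],
                 latent_qol(stable[gi], t0[gi], pmin(gm, t0[gi]),
                            qp$decline_depth_standard, qp$decline_window),
                 NA_real_)
    q1 <- q0
  }
  potential <- tibble::tibble(
    patient_id = gi,
    death_time_standard = t0[gi],
    death_time_new = t1[gi],
    visit_month = gm,
    qol_standard = q0,
    qol_new = q1
  )

  structure(
    list(patients = patients, qol = qol, potential = potential, config = config),
    class = "trial_data"
  )
}

#' @export
print.trial_data <- function(x, ...) {
  cat("<trial_data> scenario", x$config$scenario,
      "|", nrow(x$patients), "patients |",
      nrow(x$qol), "QOL measurements |",
      sprintf("%.1f%% censored", 100 * mean(x$patients$event == "censored")), "\n")
  invisible(x)
}

#' Write / read a simulated trial as plain CSV tables
#'
#' `write_trial_csv()` writes `patients.csv`, `qol_long.csv` and (when
#' potential outcomes are present) `truth.csv` into `dir`, plus the
#' configuration as `config.yaml`. `read_trial_csv()` rebuilds a
#' `trial_data` object from such a directory; real (non-simulated) data
#' need only the two observed tables. Times are in months, QOL in points.
#'
#' @param trial A `trial_data` object.
#' @param dir Directory to write to / read from (created if needed).
#' @return `write_trial_csv()` the directory invisibly;
#'   `read_trial_csv()` a `trial_data` list (with `potential = NULL` and
#'   `config = NULL` when those files are absent).
#' @export
write_trial_csv <- function(trial, dir) {
  stopifnot(inherits(trial, "trial_data"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(trial$patients, file.path(dir, "patients.csv"))
  readr::write_csv(
    dplyr::rename(trial$qol, qol = "value"),
    file.path(dir, "qol_long.csv")
  )
  if (!is.null(trial$potential)) {
    readr::write_csv(trial$potential, file.path(dir, "truth.csv"))
  }
  if (!is.null(trial$config)) {
    cfg <- trial$config
    yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  }
  invisible(dir)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(dir) {
  patients <- readr::read_csv(file.path(dir, "patients.csv"),
                              show_col_types = FALSE)
  qol <- readr::read_csv(file.path(dir, "qol_long.csv"), show_col_types = FALSE)
  qol <- dplyr::rename(qol, value = "qol")
  truth_path <- file.path(dir, "truth.csv")
  potential <- if (file.exists(truth_path)) {
    readr::read_csv(truth_path, show_col_types = FALSE)
  } else {
    NULL
  }
  cfg_path <- file.path(dir, "config.yaml")
  config <- if (file.exists(cfg_path)) {
    raw <- yaml::read_yaml(cfg_path)
    trial_config(
      scenario = raw$scenario, n_patients = raw$n_patients, seed = raw$seed,
      hazard_ratio = raw$hazard_ratio, standard_rate = raw$standard_rate,
      plateau = unlist(raw$plateau), censor_rate = raw$censor_rate,
      qol_schedule = unlist(raw$qol_schedule),
      qol_params = lapply(raw$qol_params, unlist),
      qol_effect_on = raw$qol_effect_on
    )
  } else {
    NULL
  }
  structure(list(patients = patients, qol = qol, potential = potential,
                 config = config),
            class = "trial_data")
}
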