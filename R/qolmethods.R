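#' Survivor analysis: QOL summarized among patients under follow-up
#'
#' Per arm and visit, the mean, SD and count of QOL over patients still
#' under follow-up at the visit with an observed measurement. This is a
#' summary of the surviving (and uncensored) subpopulation, not a causal
#' contrast: when treatment affects survival, the subpopulations being
#' compared differ between arms.
#'
#' @param trial A `trial_data` object.
#' @return Tibble `visit_month`, `arm`, `n`, `mean`, `sd`.
#' @export
survivor_summary <- function(trial) {
  trial$qol |>
    dplyr::inner_join(trial$patients[, c("patient_id", "arm", "followup_time")],
                      by = "patient_id") |>
    dplyr::filter(.data$visit_month <= .data$followup_time) |>
    dplyr::group_by(.data$visit_month, .data$arm) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     sd = stats::sd(.data$value), .groups = "drop")
}

#' Per-visit survivor-analysis contrast (new minus standard)
#'
#' @param trial A `trial_data` object.
#' @return Tibble `visit_month`, `mean_standard`, `mean_new`, `contrast`.
#' @export
survivor_contrast <- function(trial) {
  survivor_summary(trial) |>
    dplyr::select("visit_month", "arm", "mean") |>
    tidyr::pivot_wider(names_from = "arm", values_from = "mean",
                       names_prefix = "arm") |>
    dplyr::transmute(
      visit_month = .data$visit_month,
      mean_standard = .data$arm0, mean_new = .data$arm1,
      contrast = .data$arm1 - .data$arm0
    )
}

#' QOL measurements re-indexed backward from death
#'
#' Each QOL measurement of a patient with an observed death is assigned
#' the backward time `death_time - visit_month`. Censored patients have
#' no death anchor and contribute nothing.
#'
#' @param trial A `trial_data` object.
#' @return Tibble `patient_id`, `arm`, `visit_month`, `backward_time`,
#'   `value`.
#' @export
backward_qol <- function(trial) {
  dead <- trial$patients[trial$patients$event == "death",
                         c("patient_id", "arm", "death_time")]
  trial$qol |>
    dplyr::inner_join(dead, by = "patient_id") |>
    dplyr::transmute(
      patient_id = .data$patient_id, arm = .data$arm,
      visit_month = .data$visit_month,
      backward_time = .data$death_time - .data$visit_month,
      value = .data$value
    )
}

#' Terminal-decline trajectory on the backward-from-death time scale
#'
#' Bins the backward-time measurements of decedents ([backward_qol()])
#' into `bin_width`-month intervals (labelled at the bin midpoint; no
#' interpolation between visits) and summarizes QOL per arm and bin.
#'
#' @param trial A `trial_data` object.
#' @param bin_width Bin width in months (default 3, the measurement grid).
#' @return Tibble `arm`, `backward_time` (bin midpoint), `n`, `mean`,
#'   `sd`, `backward_mean` (the within-bin mean backward time, used by
#'   [terminal_decline_fit()] as the bin's abscissa). Empty, with a
#'   warning, when no deaths are observed.
#' @export
backward_trajectory <- function(trial, bin_width = 3) {
  bq <- backward_qol(trial)
  if (nrow(bq) == 0) {
    warning("no observed deaths; terminal-decline summary is empty",
            call. = FALSE)
    return(tibble::tibble(arm = integer(), backward_time = numeric(),
                          n = integer(), mean = numeric(), sd = numeric()))
  }
  bq |>
    dplyr::mutate(bin = floor(.data$backward_time / bin_width) * bin_width +
                    bin_width / 2) |>
    dplyr::group_by(.data$arm, bin) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     sd = stats::sd(.data$value),
                     backward_mean = mean(.data$backward_time),
                     .groups = "drop") |>
    dplyr::rename(backward_time = "bin") |>
    dplyr::arrange(.data$arm, .data$backward_time)
}

#' Flat-then-linear changepoint fit of the terminal decline
#'
#' Fits, by weighted least squares over a grid of candidate knots, the
#' piecewise model that is flat at a stable level for backward times
#' beyond the knot and declines linearly to death (backward time 0)
#' before it. Returns the knot (onset of terminal decline), the stable
#' level, and the implied total drop between the stable level and the
#' value extrapolated to the moment of death.
#'
#' @param traj One arm's rows of [backward_trajectory()] (columns
#'   `backward_time`, `mean`, `n`).
#' @param knots Candidate knots in months; default a 0.75-month grid
#'   from 1.5 to 12.
#' @return List: `knot` (months before death), `stable_level` (points),
#'   `slope` (points/month), `depth` (= `slope * knot`, points),
#'   `rss`, and the per-knot profile tibble.
#' @export
terminal_decline_fit <- function(traj, knots = seq(1.5, 12, by = 0.75)) {
  stopifnot(nrow(traj) >= 3)
  b <- traj$backward_mean %||% traj$backward_time
  y <- traj$mean
  w <- traj$n
  fit_one <- function(k) {
    ramp <- pmax(0, k - b)             # months inside the decline window
    X <- cbind(1, -ramp)               # y = L - slope * ramp
    fit <- stats::lm.wfit(X, y, w)
    rss <- sum(w * fit$residuals^2)
    c(stable = unname(fit$coefficients[1]),
      slope = unname(fit$coefficients[2]), rss = rss)
  }
  prof <- t(vapply(knots, fit_one, c(stable = 0, slope = 0, rss = 0)))
  best <- which.min(prof[, "rss"])
  list(
    knot = knots[best],
    stable_level = unname(prof[best, "stable"]),
    slope = unname(prof[best, "slope"]),
    depth = unname(prof[best, "slope"]) * knots[best],
    rss = unname(prof[best, "rss"]),
    profile = tibble::tibble(knot = knots,
                             stable = prof[, "stable"],
                             slope = prof[, "slope"],
                             rss = prof[, "rss"])
  )
}

#' MMRM for repeated QOL measures
#'
#' Linear model for the post-baseline QOL measurements with categorical
#' visit, visit-by-arm interaction, and baseline QOL and sex as
#' covariates, fitted by REML with an unstructured within-patient
#' correlation and per-visit variances (falling back to compound
#' symmetry if the unstructured fit does not converge). Returns the
#' adjusted new-minus-standard difference at each visit.
#'
#' Death-truncated measurements are not imputed, implicitly or
#' otherwise: the model simply uses the measurements that exist, so the
#' fitted means carry a missing-at-random reading that is ill-defined
#' for data truncated by death; interpret descriptively with that caveat.
#'
#' @param trial A `trial_data` object.
#' @return List of class `mmrm_fit`: `estimates` (tibble `visit_month`,
#'   `diff`, `se`, `ci_lo`, `ci_hi`), `covariance`
#'   (`"unstructured"` or `"compound_symmetry"`), `converged`, `fit`
#'   (the underlying `gls` object), and `note` on truncation by death.
#' @export
fit_mmrm <- function(trial) {
  sched <- sort(unique(trial$qol$visit_month))
  post <- setdiff(sched, 0)
  if (length(post) < 2) stop("need at least two post-baseline visits", call. = FALSE)
  df <- trial$qol |>
    dplyr::filter(.data$visit_month > 0) |>
    dplyr::inner_join(
      trial$patients[, c("patient_id", "arm", "sex", "baseline_qol")],
      by = "patient_id"
    ) |>
    dplyr::filter(!is.na(.data$baseline_qol)) |>
    dplyr::mutate(
      visit_f = factor(.data$visit_month, levels = post),
      visit_idx = as.integer(.data$visit_f)
    ) |>
    as.data.frame()
  if (length(unique(df$arm)) < 2) stop("both arms required", call. = FALSE)

  form <- value ~ baseline_qol + sex + visit_f + visit_f:arm
  fit <- tryCatch(
    nlme::gls(form, data = df, method = "REML",
              correlation = nlme::corSymm(form = ~visit_idx | patient_id),
              weights = nlme::varIdent(form = ~1 | visit_f),
              control = nlme::glsControl(maxIter = 100, msMaxIter = 100)),
    error = function(e) NULL
  )
  covariance <- "unstructured"
  converged <- TRUE
  if (is.null(fit)) {
    covariance <- "compound_symmetry"
    converged <- FALSE
    fit <- nlme::gls(form, data = df, method = "REML",
                     correlation = nlme::corCompSymm(form = ~1 | patient_id))
  }
  cf <- stats::coef(fit)
  vc <- stats::vcov(fit)
  terms <- paste0("visit_f", post, ":arm")
  est <- cf[terms]
  se <- sqrt(diag(vc)[terms])
  structure(
    list(
      estimates = tibble::tibble(
        visit_month = post, diff = unname(est), se = unname(se),
        ci_lo = unname(est - 1.96 * se), ci_hi = unname(est + 1.96 * se)
      ),
      covariance = covariance, converged = converged, fit = fit,
      note = paste("QOL values truncated by death are not implicitly",
                   "imputed; the estimand is ill-defined under death.")
    ),
    class = "mmrm_fit"
  )
}

#' @export
print.mmrm_fit <- function(x, ...) {
  cat("<mmrm_fit>", x$covariance, "covariance;",
      if (x$converged) "converged" else "fallback used", "\n")
  print(x$estimates)
  cat("Note:", x$note, "\n")
  invisible(x)
}

#' True survivor average causal effect from potential outcomes
#'
#' For each scheduled visit `m`, the always-survivor stratum is the set
#' of patients whose potential death times under both arms exceed `m`;
#' the SACE is the mean difference of the noise-free latent potential
#' QOL values (new minus standard) over that stratum. Available for
#' simulated data only, where the potential outcomes are known.
#'
#' @param trial A `trial_data` object carrying `potential`.
#' @return Tibble `visit_month`, `n_always` (stratum size),
#'   `mean_standard`, `mean_new`, `contrast`; visits with an empty
#'   stratum are reported with `NA` means and `n_always = 0`.
#' @export
sace_truth <- function(trial) {
  po <- trial$potential
  if (is.null(po)) stop("potential outcomes not available", call. = FALSE)
  safe_mean <- function(x) if (length(x) == 0) NA_real_ else mean(x)
  po |>
    dplyr::mutate(always = .data$death_time_standard > .data$visit_month &
                    .data$death_time_new > .data$visit_month) |>
    dplyr::group_by(.data$visit_month) |>
    dplyr::summarise(
      n_always = sum(.data$always),
      mean_standard = safe_mean(.data$qol_standard[.data$always]),
      mean_new = safe_mean(.data$qol_new[.data$always]),
      .groups = "drop"
    ) |>
    dplyr::mutate(contrast = .data$mean_new - .data$mean_standard)
}

#' Survival-probability-weighted SACE estimator
#'
#' Estimates the SACE at each visit from observed data under the
#' explainable-non-random-survival assumption: per arm, a binary
#' regression of survival-to-visit on baseline covariates is fitted;
#' each observed survivor is then weighted by the predicted probability
#' of surviving to the visit under the *other* arm, reweighting both
#' arms to the always-survivor stratum. The weighted mean QOL contrast
#' per visit estimates the SACE.
#'
#' @param trial A `trial_data` object.
#' @param formula RHS formula of baseline covariates for the survival
#'   model (default `~ baseline_qol + sex`). Use `~ 1` for constant
#'   weights, in which case the estimate reduces exactly to the
#'   survivor-analysis contrast.
#' @param visits Visits to estimate at; default all post-baseline
#'   scheduled visits.
#' @return Tibble `visit_month`, `n_standard`, `n_new`,
#'   `mean_standard`, `mean_new`, `contrast`, `min_weight`,
#'   `max_weight`. Visits where a survival model cannot be fitted are
#'   dropped with a warning.
#' @export
sace_weighted <- function(trial, formula = ~ baseline_qol + sex,
                          visits = NULL) {
  pts <- trial$patients
  sched <- sort(unique(trial$qol$visit_month))
  if (is.null(visits)) visits <- setdiff(sched, 0)
  one_visit <- function(m) {
    died_by_m <- !is.na(pts$death_time) & pts$death_time <= m
    surv_known <- pts$followup_time >= m
    known <- died_by_m | surv_known
    dat <- pts[known, ]
    dat$surv <- as.integer(!(!is.na(dat$death_time) & dat$death_time <= m))
    fits <- lapply(c(0L, 1L), function(a) {
      d <- dat[dat$arm == a, ]
      if (length(unique(d$surv)) < 2) {
        return(list(const = mean(d$surv)))
      }
      tryCatch(
        stats::glm(stats::update(formula, surv ~ .), data = d,
                   family = stats::binomial()),
        warning = function(w) suppressWarnings(
          stats::glm(stats::update(formula, surv ~ .), data = d,
                     family = stats::binomial())
        ),
        error = function(e) list(const = mean(d$surv))
      )
    })
    predict_surv <- function(fit, newdata) {
      if (!is.null(fit$const)) rep(fit$const, nrow(newdata))
      else stats::predict(fit, newdata = newdata, type = "response")
    }
    qol_m <- trial$qol[trial$qol$visit_month == m, c("patient_id", "value")]
    obs <- dplyr::inner_join(pts[pts$followup_time >= m, ], qol_m,
                             by = "patient_id")
    if (!all(c(0L, 1L) %in% obs$arm)) return(NULL)
    # weight by predicted survival under the opposite arm
    w <- ifelse(obs$arm == 1L,
                predict_surv(fits[[1]], obs),
                predict_surv(fits[[2]], obs))
    m0 <- stats::weighted.mean(obs$value[obs$arm == 0L], w[obs$arm == 0L])
    m1 <- stats::weighted.mean(obs$value[obs$arm == 1L], w[obs$arm == 1L])
    tibble::tibble(
      visit_month = m,
      n_standard = sum(obs$arm == 0L), n_new = sum(obs$arm == 1L),
      mean_standard = m0, mean_new = m1, contrast = m1 - m0,
      min_weight = min(w), max_weight = max(w)
    )
  }
  out <- dplyr::bind_rows(lapply(visits, one_visit))
  if (nrow(out) < length(visits)) {
    warning("some visits had no observed survivors in one arm and were dropped",
            call. = FALSE)
  }
  out
}
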