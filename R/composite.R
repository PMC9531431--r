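#' Prioritized composite score U
#'
#' Scores each patient by the composite that ranks death ahead of QOL:
#' the survival time when death occurs by the cutoff `t`, and `QOL(t) + t`
#' for patients alive at `t`, so that higher values are better and any
#' survivor outranks any death. Death at exactly `t` counts as the death
#' branch. Patients censored before `t` without a death (or alive at `t`
#' with no QOL measurement) carry an undefined score.
#'
#' @param death_time Death time in months, `NA` when no death observed.
#' @param qol_at_t QOL at the cutoff visit (points), `NA` when missing.
#' @param followup Follow-up time in months.
#' @param t Cutoff in months (default 12).
#' @return A tibble with columns `branch`
#'   (`"death"`, `"survivor"`, `"undefined"`) and `u` (the score, `NA`
#'   when undefined). Vectorized over patients.
#' @export
#' @examples
#' score_u(death_time = 8, qol_at_t = NA, followup = 8)        # U = 8
#' score_u(death_time = NA, qol_at_t = 78, followup = 15)      # U = 90
score_u <- function(death_time, qol_at_t, followup, t = 12) {
  if (t <= 0) stop("`t` must be positive", call. = FALSE)
  if (any(followup < 0, na.rm = TRUE) || any(death_time < 0, na.rm = TRUE)) {
    stop("times must be nonnegative", call. = FALSE)
  }
  dead_by_t <- !is.na(death_time) & death_time <= t
  alive_at_t <- !dead_by_t & followup >= t
  branch <- dplyr::case_when(
    dead_by_t ~ "death",
    alive_at_t & !is.na(qol_at_t) ~ "survivor",
    .default = "undefined"
  )
  u <- dplyr::case_when(
    branch == "death" ~ death_time,
    branch == "survivor" ~ qol_at_t + t,
    .default = NA_real_
  )
  tibble::tibble(branch = branch, u = u)
}

#' Per-patient composite scores for a trial
#'
#' Convenience wrapper joining each patient with their QOL measurement at
#' the cutoff visit and applying [score_u()].
#'
#' @param trial A `trial_data` object.
#' @param t Cutoff month (must be a scheduled visit for the QOL branch to
#'   be populated; default 12).
#' @return The `patients` tibble with `qol_at_t`, `branch` and `u` added.
#' @export
patient_scores <- function(trial, t = 12) {
  qol_t <- trial$qol[trial$qol$visit_month == t, c("patient_id", "value")]
  names(qol_t)[2] <- "qol_at_t"
  df <- dplyr::left_join(trial$patients, qol_t, by = "patient_id")
  s <- score_u(df$death_time, df$qol_at_t, df$followup_time, t = t)
  dplyr::bind_cols(df, s)
}

#' Combined two-part distribution curve of the composite score
#'
#' Builds the graphical display of the prioritized composite outcome for
#' one arm: a cumulative incidence curve of death on `[0, t]` (one minus
#' the Kaplan-Meier survival estimate, so censoring is handled by the
#' product-limit method), continued past `t` by the cumulative
#' distribution of QOL among patients under follow-up at `t`, scaled to
#' start at the death curve's value at `t`. The x-axis is mapped to
#' `[0, 1]` with the time part occupying `[0, split_fraction]` and the
#' QOL part the remainder (over the fixed instrument range by default).
#'
#' @param patients One arm's patient tibble (needs `followup_time`,
#'   `event`, and `qol_at_t` as produced by [patient_scores()]).
#' @param t Cutoff month (default 12).
#' @param split_fraction Axis share of the time part (default 0.5).
#' @param qol_range QOL axis range for the right part (default `c(0, 100)`).
#' @param arm_label Optional label stored with the curve.
#' @return An object of class `combined_curve`: a list with tibbles
#'   `left` (`time`, `cumprob`, `axis_x`) and `right`
#'   (`qol`, `cumprob`, `axis_x`), the death probability `F_t` at `t`,
#'   the number of survivors contributing to the right part
#'   `n_survivors`, and the axis metadata.
#' @export
combined_curve <- function(patients, t = 12, split_fraction = 0.5,
                           qol_range = c(0, 100), arm_label = NULL) {
  stopifnot(nrow(patients) > 0, t > 0, split_fraction > 0, split_fraction < 1)
  status <- as.integer(patients$event == "death")
  km <- survival::survfit(survival::Surv(patients$followup_time, status) ~ 1)
  keep <- km$time <= t & km$n.event > 0
  left <- tibble::tibble(
    time = c(0, km$time[keep]),
    cumprob = c(0, 1 - km$surv[keep])
  )
  f_t <- max(left$cumprob)
  left$axis_x <- split_fraction * left$time / t

  survivors <- patients[patients$followup_time >= t & !is.na(patients$qol_at_t), ]
  if (nrow(survivors) == 0) {
    right <- tibble::tibble(qol = numeric(), cumprob = numeric(),
                            axis_x = numeric())
    warning("no patient under follow-up at t with QOL observed; ",
            "right segment is empty", call. = FALSE)
  } else {
    q <- sort(survivors$qol_at_t)
    qs <- unique(q)
    ecdf_q <- cumsum(tabulate(match(q, qs))) / length(q)
    right <- tibble::tibble(
      qol = c(qol_range[1], qs),
      cumprob = c(f_t, f_t + (1 - f_t) * ecdf_q),
      axis_x = split_fraction + (1 - split_fraction) *
        (c(qol_range[1], qs) - qol_range[1]) / diff(qol_range)
    )
  }
  structure(
    list(left = left, right = right, t = t, F_t = f_t,
         n_survivors = nrow(survivors),
         split_fraction = split_fraction, qol_range = qol_range,
         arm_label = arm_label),
    class = "combined_curve"
  )
}

#' @export
print.combined_curve <- function(x, ...) {
  cat("<combined_curve>", if (!is.null(x$arm_label)) paste0("arm ", x$arm_label),
      sprintf("t = %g, F(t) = %.3f, %d survivors in QOL part\n",
              x$t, x$F_t, x$n_survivors))
  invisible(x)
}

#' Quantile of the combined composite distribution
#'
#' Left-continuous inverse along the concatenated time-then-QOL domain:
#' the smallest domain point whose cumulative probability reaches `p`.
#' Quantiles up to the death probability at the cutoff fall in the time
#' part; larger ones fall in the QOL part.
#'
#' @param curve A [combined_curve()].
#' @param p Probability in (0, 1); vectorized.
#' @return A tibble with columns `p`, `domain` (`"time"`, `"qol"` or
#'   `"not_estimable"`), `value` (months or QOL points) and `axis_x`.
#' @export
percentile_u <- function(curve, p) {
  stopifnot(inherits(curve, "combined_curve"), all(p > 0 & p < 1))
  one <- function(pp) {
    jumps <- curve$left[curve$left$time > 0 | curve$left$cumprob > 0, ]
    if (nrow(jumps) > 0 && any(jumps$cumprob >= pp)) {
      i <- which(jumps$cumprob >= pp)[1]
      return(tibble::tibble(p = pp, domain = "time",
                            value = jumps$time[i], axis_x = jumps$axis_x[i]))
    }
    r <- curve$right
    if (nrow(r) > 0 && any(r$cumprob >= pp)) {
      i <- which(r$cumprob >= pp)[1]
      return(tibble::tibble(p = pp, domain = "qol",
                            value = r$qol[i], axis_x = r$axis_x[i]))
    }
    tibble::tibble(p = pp, domain = "not_estimable",
                   value = NA_real_, axis_x = NA_real_)
  }
  dplyr::bind_rows(lapply(p, one))
}

# status of one patient relative to the cutoff:
#   dead (death <= t), survivor (followup >= t), unknown (censored before t)
.composite_status <- function(patients, t) {
  dead <- !is.na(patients$death_time) & patients$death_time <= t
  survivor <- !dead & patients$followup_time >= t
  tibble::tibble(
    type = dplyr::case_when(dead ~ "dead", survivor ~ "survivor",
                            .default = "unknown"),
    dtime = ifelse(dead, patients$death_time, NA_real_),
    qol = ifelse(survivor, patients$qol_at_t, NA_real_),
    ctime = ifelse(!dead & !survivor, patients$followup_time, NA_real_)
  )
}

#' Generalized pairwise comparison of two patients
#'
#' Compares a new-arm patient `a` with a standard-arm patient `b` under
#' the two-level priority: (1) time to death up to the cutoff `t`
#' (earlier death is worse; the ordering is used when it is observable
#' despite censoring, including when one patient's follow-up is known to
#' extend past the other's death) and (2) QOL at `t` among patients alive
#' at `t` (lower QOL is worse; equality within `margin` is a tie). Pairs
#' whose ordering censoring leaves undecided are uninformative.
#'
#' @param a,b One-row patient records (as in [patient_scores()] output),
#'   `a` from the new arm, `b` from the standard arm.
#' @param t Cutoff month (default 12).
#' @param margin Clinically relevant QOL margin treated as a tie
#'   (default 0: exact equality).
#' @return One of `"win"`, `"loss"`, `"tie"`, `"uninformative"`, from
#'   `a`'s perspective.
#' @export
pairwise_compare <- function(a, b, t = 12, margin = 0) {
  sa <- .composite_status(a, t)
  sb <- .composite_status(b, t)
  if (sa$type == "dead" && sb$type == "dead") {
    if (sa$dtime > sb$dtime) return("win")
    if (sa$dtime < sb$dtime) return("loss")
    return("tie")
  }
  if (sa$type == "dead") {
    if (sb$type == "survivor") return("loss")
    # b censored before t: b known alive at ctime
    if (sb$ctime >= sa$dtime) return("loss")
    return("uninformative")
  }
  if (sb$type == "dead") {
    if (sa$type == "survivor") return("win")
    if (sa$ctime >= sb$dtime) return("win")
    return("uninformative")
  }
  if (sa$type == "survivor" && sb$type == "survivor") {
    if (is.na(sa$qol) || is.na(sb$qol)) return("uninformative")
    if (sa$qol > sb$qol + margin) return("win")
    if (sb$qol > sa$qol + margin) return("loss")
    return("tie")
  }
  "uninformative"
}

# count of elements of sorted vector x that are < v (strict) or <= v
.count_below <- function(x, v, strict = TRUE) {
  findInterval(v, x, left.open = strict)
}

#' Win statistics for the prioritized composite outcome
#'
#' Classifies every between-arm pair with the [pairwise_compare()] rule
#' (using order-statistics counting, so large trials are handled without
#' enumerating pairs) and returns the win ratio and net benefit, with
#' optional bootstrap confidence intervals resampling patients within arm.
#'
#' @param trial A `trial_data` object, or a patient tibble already
#'   containing `qol_at_t` (see [patient_scores()]).
#' @param t Cutoff month (default 12).
#' @param margin QOL tie margin (default 0).
#' @param bootstrap_reps Number of bootstrap replicates for percentile
#'   CIs (default 0: no CI).
#' @param conf_level CI level (default 0.95).
#' @return A one-row tibble: `wins`, `losses`, `ties`, `uninformative`
#'   (counts over all `n_new * n_standard` pairs), `win_ratio`,
#'   `net_benefit`, `infinite_ratio` flag, and CI bounds when requested.
#' @export
win_statistics <- function(trial, t = 12, margin = 0,
                           bootstrap_reps = 0, conf_level = 0.95) {
  pts <- if (inherits(trial, "trial_data")) patient_scores(trial, t) else trial
  stopifnot(all(c(0, 1) %in% pts$arm))
  counts_fun <- function(pn, ps) {
    a <- .composite_status(pn, t)
    b <- .composite_status(ps, t)
    Da <- sort(a$dtime[a$type == "dead"]); Db <- sort(b$dtime[b$type == "dead"])
    Qa <- sort(a$qol[a$type == "survivor" & !is.na(a$qol)])
    Qb <- sort(b$qol[b$type == "survivor" & !is.na(b$qol)])
    Sa <- sum(a$type == "survivor"); Sb <- sum(b$type == "survivor")
    Ca <- sort(a$ctime[a$type == "unknown"]); Cb <- sort(b$ctime[b$type == "unknown"])
    n_pairs <- nrow(a) * nrow(b)
    wins <- Sa * length(Db) +
      sum(.count_below(Qb, Qa - margin, strict = TRUE)) +
      sum(.count_below(Db, Da, strict = TRUE)) +
      sum(.count_below(Db, Ca, strict = FALSE))
    losses <- Sb * length(Da) +
      sum(.count_below(Qa, Qb - margin, strict = TRUE)) +
      sum(.count_below(Da, Db, strict = TRUE)) +
      sum(.count_below(Da, Cb, strict = FALSE))
    ties_death <- sum(.count_below(Db, Da, strict = FALSE) -
                        .count_below(Db, Da, strict = TRUE))
    ties_qol <- length(Qa) * length(Qb) -
      sum(.count_below(Qb, Qa - margin, strict = TRUE)) -
      sum(.count_below(Qa, Qb - margin, strict = TRUE))
    ties <- ties_death + ties_qol
    c(wins = wins, losses = losses, ties = ties,
      uninformative = n_pairs - wins - losses - ties, n_pairs = n_pairs)
  }
  pn <- pts[pts$arm == 1L, ]
  ps <- pts[pts$arm == 0L, ]
  cc <- counts_fun(pn, ps)
  wr <- if (cc["losses"] == 0) Inf else unname(cc["wins"] / cc["losses"])
  nb <- unname((cc["wins"] - cc["losses"]) / cc["n_pairs"])
  out <- tibble::tibble(
    wins = unname(cc["wins"]), losses = unname(cc["losses"]),
    ties = unname(cc["ties"]), uninformative = unname(cc["uninformative"]),
    n_pairs = unname(cc["n_pairs"]),
    win_ratio = wr, net_benefit = nb,
    infinite_ratio = !is.finite(wr)
  )
  if (bootstrap_reps > 0) {
    alpha <- (1 - conf_level) / 2
    boot <- replicate(bootstrap_reps, {
      bn <- pn[sample.int(nrow(pn), replace = TRUE), ]
      bs <- ps[sample.int(nrow(ps), replace = TRUE), ]
      b <- counts_fun(bn, bs)
      c(wr = if (b["losses"] == 0) Inf else unname(b["wins"] / b["losses"]),
        nb = unname((b["wins"] - b["losses"]) / b["n_pairs"]))
    })
    out$win_ratio_lo <- unname(stats::quantile(boot["wr", ], alpha, na.rm = TRUE))
    out$win_ratio_hi <- unname(stats::quantile(boot["wr", ], 1 - alpha, na.rm = TRUE))
    out$net_benefit_lo <- unname(stats::quantile(boot["nb", ], alpha))
    out$net_benefit_hi <- unname(stats::quantile(boot["nb", ], 1 - alpha))
  }
  out
}
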