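test_that("survivor_summary restricts to patients under follow-up", {
  patients <- tibble::tibble(
    patient_id = 1:4, arm = c(0L, 0L, 1L, 1L),
    followup_time = c(5, 9, 9, 9),
    event = c("death", "censored", "death", "censored")
  )
  qol <- tibble::tibble(
    patient_id = c(1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L, 4L, 4L, 4L),
    visit_month = c(0, 3, 0, 3, 6, 0, 3, 6, 0, 3, 6),
    value = c(80, 70, 90, 85, 80, 60, 65, 70, 70, 75, 80)
  )
  s <- survivor_summary(make_trial(patients, qol))
  # patient 1 dies at 5: absent from visit 6 onward
  v6 <- s[s$visit_month == 6, ]
  expect_equal(v6$n[v6$arm == 0], 1)
  expect_equal(v6$mean[v6$arm == 0], 80)
  expect_equal(v6$mean[v6$arm == 1], mean(c(70, 80)))
  v0 <- s[s$visit_month == 0, ]
  expect_equal(v0$mean[v0$arm == 0], mean(c(80, 90)))
  expect_equal(v0$n, c(2L, 2L))
})

test_that("backward_qol re-indexes decedent measurements from death", {
  patients <- tibble::tibble(
    patient_id = 1:2, arm = 0L,
    followup_time = c(10, 8), event = c("death", "censored")
  )
  qol <- tibble::tibble(
    patient_id = c(1L, 1L, 1L, 2L, 2L),
    visit_month = c(3, 6, 9, 3, 6),
    value = c(80, 75, 65, 80, 80)
  )
  bq <- backward_qol(make_trial(patients, qol))
  # death at 10, visits 3, 6, 9 -> backward times 7, 4, 1
  expect_equal(bq$backward_time, c(7, 4, 1))
  # censored patients contribute nothing
  expect_false(any(bq$patient_id == 2L))
  expect_warning(
    backward_trajectory(make_trial(dplyr::mutate(patients,
                                                 event = "censored"), qol)),
    "no observed deaths"
  )
})

test_that("noise-free data recover the flat-then-ramp shape exactly", {
  cfg <- trial_config(
    scenario = 1, n_patients = 800, seed = 31,
    qol_params = list(stable_sd = 0, noise_sd = 0, sex_effect = 0)
  )
  tr <- simulate_trial(cfg)
  td <- backward_trajectory(tr)
  td0 <- td[td$arm == 0, ]
  # bins entirely beyond the decline window sit at the stable level
  expect_true(all(abs(td0$mean[td0$backward_time > 6] - 80) < 1e-9))
  fit <- terminal_decline_fit(td0)
  expect_equal(fit$knot, 6)
  expect_equal(fit$stable_level, 80, tolerance = 1e-6)
  expect_equal(fit$depth, 20, tolerance = 1e-6)
  # new arm has the shallower decline in scenario 1
  fit1 <- terminal_decline_fit(td[td$arm == 1, ])
  expect_equal(fit1$depth, 10, tolerance = 1e-6)
})

test_that("MMRM adjusted differences match raw means on complete data", {
  # complete balanced data: no death, no censoring, null covariate effects
  set.seed(55)
  n <- 160
  sched <- c(0, 3, 6, 9)
  patients <- tibble::tibble(
    patient_id = seq_len(n), arm = rep(c(0L, 1L), n / 2),
    sex = rbinom(n, 1, 0.5),
    followup_time = 12, event = "censored", death_time = NA_real_
  )
  true_diff <- c(2, 4, 6)
  qol <- tidyr::expand_grid(patient_id = seq_len(n), visit_month = sched) |>
    dplyr::left_join(patients[, c("patient_id", "arm")], by = "patient_id") |>
    dplyr::mutate(value = 70 + 0.5 * visit_month +
                    true_diff[pmax(visit_month / 3, 1)] * arm *
                      (visit_month > 0) +
                    rnorm(dplyr::n(), 0, 4)) |>
    dplyr::select(-arm)
  base <- qol$value[qol$visit_month == 0]
  patients$baseline_qol <- base[order(qol$patient_id[qol$visit_month == 0])]
  tr <- make_trial(patients, qol)
  fit <- fit_mmrm(tr)
  raw <- survivor_contrast(tr)
  raw <- raw[raw$visit_month > 0, ]
  expect_equal(fit$estimates$visit_month, c(3, 6, 9))
  # covariates are independent of outcome, so adjustment changes little
  expect_lt(max(abs(fit$estimates$diff - raw$contrast)), 1)
  # and the generating differences are recovered within 3 SEs
  expect_true(all(abs(fit$estimates$diff - true_diff) <
                    3 * fit$estimates$se + 1e-9))
  expect_true(fit$covariance %in% c("unstructured", "compound_symmetry"))
  expect_match(fit$note, "not implicitly imputed")
})

test_that("identical arms give near-zero MMRM differences", {
  tr <- small_trial(scenario = 3, n = 300, seed = 77,
                    qol_params = list(decline_depth_new = 20))
  # scenario 3 with equal depths and HR 1: arms exchangeable
  fit <- fit_mmrm(tr)
  expect_true(all(abs(fit$estimates$diff) < 3 * fit$estimates$se + 1e-9))
})

test_that("MMRM recovers generating means under MAR dropout", {
  set.seed(66)
  n <- 300
  sched <- c(0, 3, 6)
  mu <- c(70, 72, 74)
  arm_shift <- c(0, 3, 5)
  Sigma <- 16 * (0.5 + 0.5 * diag(3))
  L <- chol(Sigma)
  arm <- rep(c(0L, 1L), n / 2)
  y <- matrix(rnorm(n * 3), n, 3) %*% L +
    matrix(mu, n, 3, byrow = TRUE) +
    outer(arm, arm_shift)
  # dropout at visit 3 (index 3) depends only on the previous observed value
  drop3 <- rbinom(n, 1, plogis(-(y[, 2] - 70) / 4)) == 1
  rows <- list()
  for (i in seq_len(n)) {
    keep <- if (drop3[i]) 1:2 else 1:3
    rows[[i]] <- tibble::tibble(patient_id = i, visit_month = sched[keep],
                                value = y[i, keep])
  }
  qol <- dplyr::bind_rows(rows)
  patients <- tibble::tibble(
    patient_id = seq_len(n), arm = arm, sex = rbinom(n, 1, 0.5),
    baseline_qol = y[, 1], followup_time = 12, event = "censored",
    death_time = NA_real_
  )
  fit <- fit_mmrm(make_trial(patients, qol))
  # the visit-6 contrast is observed under MAR; must recover the truth
  est6 <- fit$estimates[fit$estimates$visit_month == 6, ]
  expect_lt(abs(est6$diff - 5), 3.5 * est6$se)
})

test_that("sace_truth uses the always-survivor stratum", {
  # scenario 4: the true SACE is identically zero
  tr4 <- small_trial(scenario = 4, n = 600, seed = 41)
  truth4 <- sace_truth(tr4)
  nonempty <- truth4[truth4$n_always > 0, ]
  expect_true(nrow(nonempty) > 0)
  expect_true(all(abs(nonempty$contrast) < 1e-12))

  # HR = 1: always survivors are exactly the patients with T > m
  # (moderate stable level so the 0-100 clipping never binds and the
  # closed-form ramp oracle applies exactly)
  tr3 <- small_trial(scenario = 3, n = 400, seed = 42,
                     qol_params = list(stable_mean = 70, stable_sd = 4))
  truth3 <- sace_truth(tr3)
  po <- dplyr::distinct(tr3$potential, patient_id, .keep_all = TRUE)
  for (m in c(0, 6, 12)) {
    expect_equal(truth3$n_always[truth3$visit_month == m],
                 sum(po$death_time_standard > m))
  }
  # closed form: contrast = (D0 - D1)/delta * mean ramp over the stratum
  qp <- tr3$config$qol_params
  for (m in c(3, 6, 9)) {
    alive <- po$death_time_standard > m
    gap <- po$death_time_standard[alive] - m
    ramp <- pmax(0, qp$decline_window - gap) / qp$decline_window
    expected <- (qp$decline_depth_standard - qp$decline_depth_new) * mean(ramp)
    expect_equal(truth3$contrast[truth3$visit_month == m], expected,
                 tolerance = 1e-9)
  }
})

test_that("always-survivor strata are nested across visits", {
  tr <- small_trial(scenario = 1, n = 500, seed = 43)
  po <- dplyr::distinct(tr$potential, patient_id, .keep_all = TRUE)
  sched <- sort(unique(tr$potential$visit_month))
  prev <- NULL
  for (m in sched) {
    cur <- po$patient_id[po$death_time_standard > m & po$death_time_new > m]
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("constant weights reduce the weighted SACE to the survivor contrast", {
  tr <- small_trial(scenario = 1, n = 400, seed = 44)
  sw <- sace_weighted(tr, formula = ~1)
  sc <- survivor_contrast(tr)
  j <- dplyr::inner_join(sw, sc, by = "visit_month",
                         suffix = c("_w", "_s"))
  expect_equal(j$contrast_w, j$contrast_s, tolerance = 1e-12)
})

test_that("the weighted estimator recovers the SACE when survival is unaffected", {
  # HR = 1 with rank preservation: survivors are the always survivors,
  # so the weighted estimate must match the true SACE up to noise
  tr <- small_trial(scenario = 3, n = 4000, seed = 45)
  sw <- sace_weighted(tr)
  truth <- sace_truth(tr)
  j <- dplyr::inner_join(sw, truth, by = "visit_month")
  mc_se <- 2 * 9.5 / sqrt(pmin(j$n_standard, j$n_new))
  expect_true(all(abs(j$contrast.x - j$contrast.y) < 3 * mc_se))
  expect_true(all(sw$min_weight >= 0 & sw$max_weight <= 1))
})
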