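test_that("score_u follows the death / survivor / undefined branching", {
  s <- score_u(death_time = 8, qol_at_t = NA, followup = 8, t = 12)
  expect_equal(s$branch, "death")
  expect_equal(s$u, 8)
  s <- score_u(death_time = NA, qol_at_t = 78, followup = 15, t = 12)
  expect_equal(s$branch, "survivor")
  expect_equal(s$u, 90)
  # death at exactly the cutoff is the death branch
  s <- score_u(death_time = 12, qol_at_t = 80, followup = 12, t = 12)
  expect_equal(s$branch, "death")
  expect_equal(s$u, 12)
  # censored before t without death: undefined
  s <- score_u(death_time = NA, qol_at_t = NA, followup = 5, t = 12)
  expect_equal(s$branch, "undefined")
  expect_true(is.na(s$u))
  expect_error(score_u(-1, NA, 3), "nonnegative")
  expect_error(score_u(3, NA, 3, t = 0), "positive")
})

test_that("combined_curve matches a hand-built product-limit + scaled ECDF", {
  pts <- make_trial(tibble::tibble(
    patient_id = 1:6, arm = 1L,
    followup_time = c(4, 6, 10, 12, 13, 14),
    event = c("death", "censored", "death", "censored", "censored", "censored")
  ))$patients
  pts$qol_at_t <- c(NA, NA, NA, 70, 80, 80)
  cc <- combined_curve(pts, t = 12)
  # product-limit: S(4) = 5/6, censor at 6, S(10) = 5/6 * 3/4 = 5/8
  expect_equal(cc$left$time, c(0, 4, 10))
  expect_equal(cc$left$cumprob, c(0, 1 / 6, 3 / 8))
  expect_equal(cc$F_t, 3 / 8)
  # right part: F(t) + (1 - F(t)) * ECDF over {70, 80, 80}
  expect_equal(cc$right$qol, c(0, 70, 80))
  expect_equal(cc$right$cumprob, c(3 / 8, 3 / 8 + 5 / 8 * 1 / 3, 1))
  # axis mapping: halves by default, right part starts exactly at the split
  expect_equal(cc$left$axis_x, 0.5 * cc$left$time / 12)
  expect_equal(cc$right$axis_x[1], 0.5)
})

test_that("without censoring the combined curve is the ECDF of per-patient U", {
  for (seed in 1:4) {
    tr <- simulate_trial(trial_config(scenario = 2, n_patients = 18,
                                      seed = seed, censor_rate = 1e-9))
    sc <- patient_scores(tr, t = 12)
    expect_true(all(sc$branch != "undefined"))
    for (a in c(0, 1)) {
      arm_sc <- sc[sc$arm == a, ]
      if (nrow(arm_sc) == 0) next
      cc <- suppressWarnings(combined_curve(arm_sc, t = 12))
      Fu <- stats::ecdf(arm_sc$u)
      # left segment: deaths by t
      left <- cc$left[cc$left$time > 0, ]
      expect_equal(left$cumprob, Fu(left$time))
      # right segment: survivor scores QOL + t
      right <- cc$right[-1, ]
      expect_equal(right$cumprob, Fu(right$qol + 12))
    }
  }
})

test_that("percentile_u is the left-continuous inverse over both segments", {
  # uncensored scores {3, 7, 72, 92}: deaths at 3 and 7, QOL 60 and 80
  pts <- make_trial(tibble::tibble(
    patient_id = 1:4, arm = 1L,
    followup_time = c(3, 7, 13, 14),
    event = c("death", "death", "censored", "censored")
  ))$patients
  pts$qol_at_t <- c(NA, NA, 60, 80)
  cc <- combined_curve(pts, t = 12)
  q <- percentile_u(cc, c(0.5, 0.7))
  expect_equal(q$domain, c("time", "qol"))
  expect_equal(q$value, c(7, 60))
  # all patients die at month 5: every quantile is (time, 5)
  pts2 <- make_trial(tibble::tibble(
    patient_id = 1:3, arm = 1L, followup_time = c(5, 5, 5),
    event = rep("death", 3)
  ))$patients
  pts2$qol_at_t <- NA_real_
  cc2 <- suppressWarnings(combined_curve(pts2, t = 12))
  for (p in c(0.2, 0.5, 0.9)) {
    qq <- percentile_u(cc2, p)
    expect_equal(qq$domain, "time")
    expect_equal(qq$value, 5)
  }
  # p beyond F(t) falls in the QOL segment
  q3 <- percentile_u(cc, 0.9)
  expect_equal(q3$domain, "qol")
  # monotone in p along the concatenated domain
  ps <- seq(0.05, 0.95, by = 0.05)
  qs <- percentile_u(cc, ps)
  ax <- qs$axis_x
  expect_true(all(diff(ax) >= -1e-12))
})

test_that("pairwise_compare applies the death-then-QOL priority", {
  rec <- function(fu, ev, q = NA_real_) {
    p <- make_trial(tibble::tibble(patient_id = 1L, arm = 1L,
                                   followup_time = fu, event = ev))$patients
    p$qol_at_t <- q
    p
  }
  # earlier death is worse
  expect_equal(pairwise_compare(rec(3, "death"), rec(5, "death")), "loss")
  # survivors compared on QOL; lower QOL is worse
  expect_equal(pairwise_compare(rec(13, "censored", 80),
                                rec(14, "censored", 70)), "win")
  expect_equal(pairwise_compare(rec(13, "censored", 70),
                                rec(14, "censored", 70)), "tie")
  # censoring before the other's death precludes ordering
  expect_equal(pairwise_compare(rec(4, "censored"), rec(8, "death")),
               "uninformative")
  # but censoring after it forces the ordering
  expect_equal(pairwise_compare(rec(9, "censored"), rec(8, "death")), "win")
  # death vs survivor
  expect_equal(pairwise_compare(rec(8, "death"), rec(13, "censored", 50)),
               "loss")
})

test_that("win_statistics matches exhaustive pair enumeration", {
  for (seed in 1:4) {
    tr <- simulate_trial(trial_config(scenario = 2, n_patients = 30,
                                      seed = seed))
    sc <- patient_scores(tr, t = 12)
    if (!all(c(0, 1) %in% sc$arm)) next
    ws <- win_statistics(sc, t = 12)
    brute <- enumerate_pairs(sc, t = 12)
    expect_equal(ws$wins, unname(brute["win"]))
    expect_equal(ws$losses, unname(brute["loss"]))
    expect_equal(ws$ties, unname(brute["tie"]))
    expect_equal(ws$uninformative, unname(brute["uninformative"]))
    expect_equal(ws$wins + ws$losses + ws$ties + ws$uninformative, ws$n_pairs)
  }
})

test_that("a 2x2 toy set reproduces counts computed by hand", {
  pts <- make_trial(tibble::tibble(
    patient_id = 1:4, arm = c(1L, 1L, 0L, 0L),
    followup_time = c(5, 13, 9, 13),
    event = c("death", "censored", "death", "censored")
  ))$patients
  pts$qol_at_t <- c(NA, 75, NA, 70)
  ws <- win_statistics(pts, t = 12)
  # pairs: (d5 vs d9) loss, (d5 vs s70) loss, (s75 vs d9) win, (s75 vs s70) win
  expect_equal(ws$wins, 2)
  expect_equal(ws$losses, 2)
  expect_equal(ws$ties, 0)
  expect_equal(ws$uninformative, 0)
  expect_equal(ws$win_ratio, 1)
  expect_equal(ws$net_benefit, 0)
})

test_that("swapping arm labels inverts the win ratio and negates net benefit", {
  tr <- small_trial(scenario = 2, n = 200, seed = 6)
  sc <- patient_scores(tr, t = 12)
  ws <- win_statistics(sc, t = 12)
  swapped <- dplyr::mutate(sc, arm = 1L - arm)
  ws2 <- win_statistics(swapped, t = 12)
  expect_equal(ws2$win_ratio, 1 / ws$win_ratio)
  expect_equal(ws2$net_benefit, -ws$net_benefit)
  expect_equal(ws2$ties, ws$ties)
  expect_equal(ws2$uninformative, ws$uninformative)
})

test_that("identical arms give win ratio 1 and net benefit 0 exactly", {
  tr <- small_trial(scenario = 1, n = 120, seed = 8)
  sc <- patient_scores(tr, t = 12)
  one_arm <- sc[sc$arm == 0L, ]
  dup <- dplyr::bind_rows(one_arm,
                          dplyr::mutate(one_arm,
                                        arm = 1L,
                                        patient_id = patient_id + 10000L))
  ws <- win_statistics(dup, t = 12)
  expect_equal(ws$win_ratio, 1)
  expect_equal(ws$net_benefit, 0)
})

test_that("zero losses flag an infinite win ratio", {
  pts <- make_trial(tibble::tibble(
    patient_id = 1:4, arm = c(1L, 1L, 0L, 0L),
    followup_time = c(13, 14, 5, 6),
    event = c("censored", "censored", "death", "death")
  ))$patients
  pts$qol_at_t <- c(80, 75, NA, NA)
  ws <- win_statistics(pts, t = 12)
  expect_equal(ws$losses, 0)
  expect_true(ws$infinite_ratio)
  expect_true(is.infinite(ws$win_ratio))
})

test_that("bootstrap confidence intervals bracket the point estimates", {
  tr <- small_trial(scenario = 1, n = 150, seed = 4)
  sc <- patient_scores(tr, t = 12)
  set.seed(99)
  ws <- win_statistics(sc, t = 12, bootstrap_reps = 60)
  expect_true(ws$net_benefit_lo <= ws$net_benefit &&
                ws$net_benefit <= ws$net_benefit_hi)
  expect_true(ws$win_ratio_lo <= ws$win_ratio &&
                ws$win_ratio <= ws$win_ratio_hi)
})
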