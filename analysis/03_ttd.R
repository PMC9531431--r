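#!/usr/bin/env Rscript
# Time-to-deterioration analysis: first of death or a >= 10-point QOL
# decline from baseline. Kaplan-Meier medians, Cox hazard ratios, and the
# cause composition of events per arm, for each scenario.

source(file.path("analysis", "00_common.R"))

res <- list()
mix <- list()

for (k in SCENARIOS) {
  tr <- study_trial(k)
  ttd <- ttd_endpoint(tr, threshold = 10)
  fit <- cox_hr(ttd)
  meds <- sapply(c(0, 1), function(a) {
    km_estimate(ttd$time[ttd$arm == a], ttd$event[ttd$arm == a] == "event")$median
  })
  res[[k]] <- tibble::tibble(
    scenario = k, hr = fit$hr, ci_lo = fit$ci_lo, ci_hi = fit$ci_hi,
    median_standard = meds[1], median_new = meds[2]
  )
  mix[[k]] <- ttd |>
    filter(event == "event") |>
    count(arm, cause) |>
    group_by(arm) |>
    mutate(share = n / sum(n), scenario = k) |>
    ungroup()
}

res <- bind_rows(res)
mix <- bind_rows(mix)

message("TTD hazard ratios and median event times (months):")
print(as.data.frame(round(res, 3)))
message("\nEvent-cause composition per arm (scenario 2 shows overlapping ",
        "curves built from different events):")
print(as.data.frame(mix))

save_table(res, "ttd_summary.csv")
save_table(mix, "ttd_cause_mix.csv")
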