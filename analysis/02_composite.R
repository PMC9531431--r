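#!/usr/bin/env Rscript
# Prioritized composite outcome: combined two-part distribution curves,
# 50th/70th percentiles of the score U, and generalized pairwise
# comparisons (win ratio, net benefit) for each scenario, with t = 12.

source(file.path("analysis", "00_common.R"))

t_cut <- 12
quantiles <- list()
wins <- list()

for (k in SCENARIOS) {
  tr <- study_trial(k)
  sc <- patient_scores(tr, t = t_cut)
  for (a in c(0, 1)) {
    cc <- combined_curve(sc[sc$arm == a, ], t = t_cut, arm_label = a)
    q <- percentile_u(cc, c(0.5, 0.7))
    quantiles[[length(quantiles) + 1]] <-
      mutate(q, scenario = k, arm = a, F_t = cc$F_t)
  }
  wins[[length(wins) + 1]] <-
    mutate(win_statistics(sc, t = t_cut), scenario = k)
}

quantiles <- bind_rows(quantiles)
wins <- bind_rows(wins)

message("\nComposite quantiles (value is months in the time domain, ",
        "QOL points in the qol domain):")
print(as.data.frame(quantiles))
message("\nWin statistics (new vs standard):")
print(as.data.frame(wins[, c("scenario", "wins", "losses", "ties",
                             "uninformative", "win_ratio", "net_benefit")]))

save_table(quantiles, "composite_quantiles.csv")
save_table(wins, "composite_win_stats.csv")
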