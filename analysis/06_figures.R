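#!/usr/bin/env Rscript
# Render the six panel types for every scenario. Figures (SVG + PNG) and
# full panel coordinates go under scratch/figures; they are display
# artefacts rebuilt on demand, while the numeric summaries live in
# results/ from the earlier drivers.

source(file.path("analysis", "00_common.R"))
suppressPackageStartupMessages(library(ggplot2))

FIG <- file.path(SCRATCH, "figures")
dir.create(FIG, recursive = TRUE, showWarnings = FALSE)

save_fig <- function(p, name, width = 5, height = 4) {
  ggsave(file.path(FIG, paste0(name, ".svg")), p, width = width,
         height = height, device = grDevices::svg)
  ggsave(file.path(FIG, paste0(name, ".png")), p, width = width,
         height = height, dpi = 150)
}

for (k in SCENARIOS) {
  tr <- study_trial(k)
  os <- os_records(tr)
  kms <- lapply(c(0, 1), function(a) {
    km_estimate(os$time[os$arm == a], os$event[os$arm == a], arm_label = a)
  })

  panel_os <- build_panel("os_km", kms)
  save_fig(plot_panel(panel_os), sprintf("scenario%d_os_km", k))

  td <- backward_trajectory(tr)
  panel_td <- build_panel("terminal_decline", td)
  save_fig(plot_panel(panel_td), sprintf("scenario%d_terminal_decline", k))

  sc <- patient_scores(tr, 12)
  ccs <- lapply(c(0, 1), function(a) {
    combined_curve(sc[sc$arm == a, ], t = 12, arm_label = a)
  })
  panel_cc <- build_panel("combined_composite", ccs)
  save_fig(plot_panel(panel_cc), sprintf("scenario%d_composite", k))

  ttd <- ttd_endpoint(tr)
  ttd_kms <- lapply(c(0, 1), function(a) {
    km_estimate(ttd$time[ttd$arm == a], ttd$event[ttd$arm == a] == "event",
                arm_label = a)
  })
  panel_ttd <- build_panel("ttd_km", ttd_kms)
  save_fig(plot_panel(panel_ttd), sprintf("scenario%d_ttd", k))

  cr <- competing_endpoint(tr)
  cifs <- lapply(c(0, 1), function(a) {
    cif_estimate(cr[cr$arm == a, ], arm_label = a)
  })
  panel_cif <- build_panel("cif", cifs, os = kms)
  save_fig(plot_panel(panel_cif), sprintf("scenario%d_cif", k))

  surv <- survivor_summary(tr)
  panel_traj <- build_panel("qol_trajectory", surv)
  save_fig(plot_panel(panel_traj), sprintf("scenario%d_survivor_qol", k))

  for (p in list(panel_os, panel_td, panel_cc, panel_ttd, panel_cif,
                 panel_traj)) {
    write_panel_csv(p, file.path(FIG, sprintf("scenario%d_%s.csv", k, p$kind)))
  }
  message("scenario ", k, ": 6 panels written")
}
message("figures under ", FIG)
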