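# Shared settings for the analysis drivers.
# Each driver re-simulates its inputs through the package (cheap and
# deterministic), so the scripts can be run independently and in any order.

suppressPackageStartupMessages(library(qolsurv))
suppressPackageStartupMessages(library(dplyr))

STUDY_SEED <- 2026L       # one seed for the whole study; scenarios share
                          # common random numbers through it
STUDY_N <- 20000L         # patients per scenario
SCENARIOS <- 1:4

RESULTS <- "results"
SCRATCH <- "scratch"      # large / binary outputs (not part of the deliverable)
dir.create(RESULTS, showWarnings = FALSE)
dir.create(SCRATCH, showWarnings = FALSE)

study_trial <- function(k, n = STUDY_N) {
  simulate_trial(trial_config(scenario = k, n_patients = n, seed = STUDY_SEED))
}

save_table <- function(x, name) {
  path <- file.path(RESULTS, name)
  readr::write_csv(x, path)
  message("wrote ", path)
  invisible(path)
}
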