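# fixtures are built in code; no data files

# hand-assembled trial_data object from patient / qol tibbles
make_trial <- function(patients, qol = NULL, potential = NULL, config = NULL) {
  defaults <- tibble::tibble(
    patient_id = integer(), arm = integer(), sex = integer(),
    baseline_qol = numeric(), followup_time = numeric(),
    event = character(), death_time = numeric()
  )
  for (nm in setdiff(names(defaults), names(patients))) {
    patients[[nm]] <- switch(
      nm,
      sex = 0L,
      baseline_qol = 80,
      death_time = ifelse(patients$event == "death", patients$followup_time,
                          NA_real_),
      stop("missing column ", nm)
    )
  }
  if (is.null(qol)) {
    qol <- tibble::tibble(patient_id = integer(), visit_month = numeric(),
                          value = numeric())
  }
  structure(list(patients = patients, qol = qol, potential = potential,
                 config = config),
            class = "trial_data")
}

# small simulated trial, cached per (scenario, n, seed) within a run
small_trial <- local({
  cache <- new.env(parent = emptyenv())
  function(scenario = 1, n = 400, seed = 1, ...) {
    key <- paste(scenario, n, seed,
                 paste(deparse(list(...)), collapse = " "))
    if (is.null(cache[[key]])) {
      cache[[key]] <- simulate_trial(
        trial_config(scenario = scenario, n_patients = n, seed = seed, ...)
      )
    }
    cache[[key]]
  }
})

# brute-force win/loss/tie/uninformative counts via pairwise_compare
enumerate_pairs <- function(pts, t = 12, margin = 0) {
  pn <- pts[pts$arm == 1L, ]
  ps <- pts[pts$arm == 0L, ]
  res <- c(win = 0, loss = 0, tie = 0, uninformative = 0)
  for (i in seq_len(nrow(pn))) {
    for (j in seq_len(nrow(ps))) {
      out <- pairwise_compare(pn[i, ], ps[j, ], t = t, margin = margin)
      res[out] <- res[out] + 1
    }
  }
  res
}

# empirical survival function (no censoring): S(t) = mean(time > t)
empirical_surv <- function(times, at) {
  vapply(at, function(x) mean(times > x), numeric(1))
}
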