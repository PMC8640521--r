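# Full-size experiment battery, run once and cached for the test session.
# All acceptance checks draw on these results so the five experiments are
# integrated exactly once per run.

.battery_env <- new.env(parent = emptyenv())

battery_results <- function(seed = 1) {
  key <- paste0("battery_", seed)
  if (!is.null(.battery_env[[key]])) return(.battery_env[[key]])
  con <- default_con()
  res <- lapply(1:5, function(e)
    run_experiment(experiment_config(e, seed = seed), connectome = con))
  .battery_env[[key]] <- res
  res
}

# with-STSD vs knockout comparison for the oddball experiment
knockout_comparison <- function(seed = 1) {
  key <- paste0("knockout_", seed)
  if (!is.null(.battery_env[[key]])) return(.battery_env[[key]])
  con <- default_con()
  base <- battery_results(seed)[[4]]
  cfg <- experiment_config(4, seed = seed)
  cfg$dynamics <- knockout_stsd(cfg$dynamics)
  ko <- run_experiment(cfg, connectome = con)
  out <- list(with = base, without = ko)
  .battery_env[[key]] <- out
  out
}
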