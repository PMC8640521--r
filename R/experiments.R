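#' Derive a per-stream seed from a master seed
#'
#' Counter-based expansion of one master seed into independent, reproducible
#' sub-streams (one per protocol / condition block), all below 2^31.
#'
#' @param master master seed (integer).
#' @param stream stream counter (small nonnegative integer).
#' @return An integer seed.
#' @export
derive_seed <- function(master, stream) {
  as.integer((as.double(master) %% 1e6 * 2017 + stream * 7919 + 1) %%
               2147483629)
}

.tau_rec_defaults <- c(1.2, 1.2, 1.2, 1.7, 1.4)

#' Configuration for one of the five mismatch-negativity experiments
#'
#' Bundles anatomy, connectivity, dynamics, MEG and protocol parameters for
#' experiments 1-5:
#' 1. omission (50-ms tones at channel 7, SOI 100 ms, 10\% omissions);
#' 2. alternation with unexpected repetitions (channels 6/9, SOI 500 ms,
#'    p = 5\%);
#' 3. local-global deviance (quintets at SOA 150 ms, 850-ms gaps, both role
#'    assignments);
#' 4. oddball (standard 9, deviant 10, SOI 500 ms) with multi-standard
#'    control (channels 4-13 equiprobable);
#' 5. anisochronous oddball (300-ms tones, gaps uniform 200-1000 ms,
#'    p = 20\%).
#'
#' The recovery time constant defaults per experiment to 1.2, 1.2, 1.2,
#' 1.7, 1.4 s.  Default protocol sizes give at least 400 epochs of the
#' condition of interest; `smoke = TRUE` scales them to at least 50 for
#' quick runs that do not match the full averaging depth.
#'
#' @param experiment integer 1..5.
#' @param seed master seed; per-protocol streams are derived from it.
#' @param smoke use reduced protocol sizes.
#' @param anatomy,connectivity,dynamics,meg component parameter objects;
#'   `dynamics` defaults to [dynamics_params()] with the experiment's
#'   tau_rec.
#' @param protocol named list of overrides merged into the experiment's
#'   default protocol parameters (e.g. `list(n_slots = 1000)`).
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(experiment, seed = 1, smoke = FALSE,
                              anatomy = default_anatomy(),
                              connectivity = connectivity_params(),
                              dynamics = NULL, meg = meg_params(),
                              protocol = list()) {
  experiment <- as.integer(experiment)
  if (!experiment %in% 1:5) stop("experiment must be 1..5")
  if (is.null(dynamics))
    dynamics <- dynamics_params(tau_rec = .tau_rec_defaults[experiment])
  proto <- switch(experiment,
    list(n_slots = if (smoke) 600L else 5000L, soi = 100, p_omit = 0.10,
         channel = 7, duration = 50),
    list(n_tones = if (smoke) 2400L else 20000L, soi = 500,
         channels = c(6, 9), p_repeat = 0.05, duration = 50),
    list(n_sequences = if (smoke) 400L else 3000L, soa = 150, gap = 850,
         x_channel = 5, y_channel = 12, duration = 50,
         p = c(0.75, 0.15, 0.10)),
    list(n_tones = if (smoke) 600L else 5000L, soi = 500, std_channel = 9,
         dev_channel = 10, p_dev = 0.10, duration = 50,
         control_channels = 4:13),
    list(n_tones = if (smoke) 300L else 2500L, duration = 300,
         gap_range = c(200, 1000), std_channel = 6, dev_channel = 9,
         p_dev = 0.20)
  )
  proto[names(protocol)] <- protocol
  window <- if (experiment == 3) c(-100, 600) else c(-100, 400)
  search <- if (experiment == 3) c(50, 500) else c(50, 350)
  structure(list(experiment = experiment, seed = seed, smoke = smoke,
                 anatomy = anatomy, connectivity = connectivity,
                 dynamics = dynamics, meg = meg, protocol = proto,
                 window = window, search = search),
            class = "experiment_config")
}

# average -> baseline -> highpass for one condition set
.process_erf <- function(sig, sequence, conditions, window, dt) {
  erf <- epoch_average(sig, sequence, conditions, window = window, dt = dt)
  erf <- baseline_correct(erf, c(window[1], 0))
  highpass_erf(erf, cutoff = 1, fs = 1000 / dt)
}

# merge erf_results sharing a time axis
.merge_erfs <- function(...) {
  parts <- list(...)
  time <- parts[[1]]$time
  for (p in parts) stopifnot(identical(p$time, time))
  .new_erf(time,
           do.call(cbind, lapply(parts, function(p) p$waveforms)),
           do.call(c, lapply(parts, function(p) p$n_epochs)),
           do.call(c, lapply(parts, function(p) p$n_dropped)),
           unique(unlist(lapply(parts, function(p) p$processing))))
}

#' Run one experiment end-to-end
#'
#' Builds the connectome, generates the protocol(s), integrates the
#' dynamics, computes per-condition ERFs (average, baseline-correct,
#' 1-Hz highpass) and the experiment's defining comparison, and evaluates
#' the qualitative checks.  Deterministic given the config seed.
#'
#' @param config an `experiment_config`.
#' @param connectome optional prebuilt `connectome` (rebuilt from the
#'   config when `NULL`).
#' @return A list of class `experiment_result` with elements `erf` (merged
#'   `erf_result`), `metrics` (per-condition peaks, difference-wave peak
#'   and latency), `checks` (named logicals), `q_range`, `g_max`,
#'   `sequences`, `seed` and `config`.
#' @export
run_experiment <- function(config, connectome = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  if (is.null(connectome))
    connectome <- build_connectome(config$anatomy, config$connectivity)
  pr <- config$protocol
  dt <- config$dynamics$dt
  seed <- config$seed
  win <- config$window
  srch <- config$search
  sim <- function(sequence)
    simulate_network(connectome, sequence, params = config$dynamics,
                     meg = config$meg)
  q_range <- c(Inf, -Inf); g_max <- 0
  note <- function(tr) {
    q_range <<- c(min(q_range[1], tr$q_range[1]),
                  max(q_range[2], tr$q_range[2]))
    g_max <<- max(g_max, tr$g_max)
  }

  if (config$experiment == 1) {
    sq <- make_omission(pr$n_slots, soi = pr$soi, p_omit = pr$p_omit,
                        channel = pr$channel, duration = pr$duration,
                        seed = derive_seed(seed, 11))
    tr <- sim(sq); note(tr)
    erf <- .process_erf(tr$meg, sq, c("standard", "deviant"), win, dt)
    mmn <- mmn_metrics(erf, "deviant", "standard", srch)
    checks <- c(omission_peak_at_least_twice_standard =
                  mmn$deviant_peak$abs_amplitude >=
                    2 * mmn$standard_peak$abs_amplitude)
    sequences <- list(omission = sq)
  } else if (config$experiment == 2) {
    sq <- make_alternating(pr$n_tones, soi = pr$soi, channels = pr$channels,
                           p_repeat = pr$p_repeat, duration = pr$duration,
                           seed = derive_seed(seed, 21))
    tr <- sim(sq); note(tr)
    erf <- .process_erf(tr$meg, sq, c("standard", "deviant"), win, dt)
    mmn <- mmn_metrics(erf, "deviant", "standard", srch)
    checks <- c(repeated_tone_beats_alternating =
                  mmn$deviant_peak$abs_amplitude >
                    mmn$standard_peak$abs_amplitude)
    sequences <- list(alternating = sq)
  } else if (config$experiment == 3) {
    sqA <- make_local_global(pr$n_sequences, soa = pr$soa, gap = pr$gap,
                             x_channel = pr$x_channel,
                             y_channel = pr$y_channel,
                             duration = pr$duration, roles = "xxxxY",
                             p = pr$p, seed = derive_seed(seed, 31))
    sqB <- make_local_global(pr$n_sequences, soa = pr$soa, gap = pr$gap,
                             x_channel = pr$x_channel,
                             y_channel = pr$y_channel,
                             duration = pr$duration, roles = "xxxxX",
                             p = pr$p, seed = derive_seed(seed, 32))
    trA <- sim(sqA); note(trA)
    trB <- sim(sqB); note(trB)
    erf <- .merge_erfs(
      .process_erf(trA$meg, sqA, "X_global_deviant", win, dt),
      .process_erf(trB$meg, sqB, "X_global_standard", win, dt))
    mmn <- mmn_metrics(erf, "X_global_deviant", "X_global_standard", srch)
    checks <- c(global_deviant_beats_global_standard =
                  mmn$deviant_peak$abs_amplitude >
                    mmn$standard_peak$abs_amplitude)
    sequences <- list(deviant_block = sqA, standard_block = sqB)
  } else if (config$experiment == 4) {
    sq <- make_oddball(pr$n_tones, soi = pr$soi,
                       std_channel = pr$std_channel,
                       dev_channel = pr$dev_channel, p_dev = pr$p_dev,
                       duration = pr$duration,
                       seed = derive_seed(seed, 41))
    sqC <- make_multistandard(pr$n_tones, soi = pr$soi,
                              channels = pr$control_channels,
                              control_channel = pr$dev_channel,
                              duration = pr$duration,
                              seed = derive_seed(seed, 42))
    tr <- sim(sq); note(tr)
    trC <- sim(sqC); note(trC)
    erf <- .merge_erfs(
      .process_erf(tr$meg, sq, c("standard", "deviant"), win, dt),
      .process_erf(trC$meg, sqC, "control", win, dt))
    mmn <- mmn_metrics(erf, "deviant", "standard", srch)
    ctrl <- peak_metric(erf, "control", srch)
    mmn$control_peak <- ctrl
    checks <- c(deviant_beats_standard =
                  mmn$deviant_peak$abs_amplitude >
                    mmn$standard_peak$abs_amplitude,
                oddball_deviant_beats_multistandard_control =
                  mmn$deviant_peak$abs_amplitude > ctrl$abs_amplitude)
    sequences <- list(oddball = sq, multistandard = sqC)
  } else {
    sq <- make_anisochronous(pr$n_tones, duration = pr$duration,
                             gap_range = pr$gap_range,
                             std_channel = pr$std_channel,
                             dev_channel = pr$dev_channel,
                             p_dev = pr$p_dev,
                             seed = derive_seed(seed, 51))
    tr <- sim(sq); note(tr)
    erf <- .process_erf(tr$meg, sq, c("standard", "deviant"), win, dt)
    mmn <- mmn_metrics(erf, "deviant", "standard", srch)
    checks <- c(deviant_beats_standard_despite_jitter =
                  mmn$deviant_peak$abs_amplitude >
                    mmn$standard_peak$abs_amplitude)
    sequences <- list(anisochronous = sq)
  }

  structure(list(experiment = config$experiment, erf = erf, metrics = mmn,
                 checks = checks, q_range = q_range, g_max = g_max,
                 sequences = sequences, seed = seed, config = config),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("experiment", x$experiment, "result\n")
  cat(sprintf("  MMN peak %.4g at %g ms\n", x$metrics$peak_amplitude,
              x$metrics$peak_latency))
  for (i in seq_along(x$checks))
    cat(sprintf("  [%s] %s\n", if (x$checks[i]) "ok" else "FAIL",
                names(x$checks)[i]))
  invisible(x)
}

#' Calibrate connectivity gains with a single-tone probe
#'
#' Scales the between-field pathway gains (feedforward plus the tied
#' feedback fraction) by a common factor chosen by bisection so that a
#' single 50-ms tone delivered from rest drives the peak core-field firing
#' rate into `target_range`, then verifies that cortical activity decays
#' below `settle_frac` of its peak within `settle_ms` after tone offset
#' and that the probe stays finite.
#'
#' @param connectivity starting `connectivity_params`.
#' @param anatomy a `network_anatomy`.
#' @param dynamics a `dynamics_params`.
#' @param target_range admissible band for the peak core firing rate.
#' @param settle_ms post-offset settling horizon, ms.
#' @param settle_frac settling criterion as a fraction of the peak rate.
#' @param channel,duration,amplitude probe tone.
#' @param max_iter bisection iterations.
#' @return list with the calibrated `connectivity_params` (`params`), the
#'   applied `scale`, and probe measurements `peak_rate` and
#'   `settle_rate`.
#' @export
calibrate_gains <- function(connectivity = connectivity_params(),
                            anatomy = default_anatomy(),
                            dynamics = dynamics_params(),
                            target_range = c(0.3, 0.8),
                            settle_ms = 600, settle_frac = 0.01,
                            channel = 7, duration = 50, amplitude = 1,
                            max_iter = 30) {
  probe_seq <- data.frame(onset = 0, duration = duration,
                          channel = channel, amplitude = amplitude,
                          condition = "probe", sequence_id = 1L)
  probe <- function(scale) {
    p <- connectivity
    p$gain_ff <- p$gain_ff * scale
    con <- build_connectome(anatomy, p)
    tr <- simulate_network(con, probe_seq, params = dynamics,
                           duration = duration + settle_ms + 200,
                           record_state = TRUE)
    core <- con$units$unit[con$units$level == "core"]
    ctx <- con$units$unit[con$units$cortical]
    rates <- firing_rate(tr$u, dynamics$theta)
    peak <- max(rates[, core])
    at <- which(tr$times >= duration + settle_ms)[1]
    settle <- max(rates[at:nrow(rates), ctx])
    list(params = p, scale = scale, peak_rate = peak, settle_rate = settle)
  }
  feasible <- function(res)
    res$peak_rate >= target_range[1] && res$peak_rate <= target_range[2] &&
      res$settle_rate <= settle_frac * res$peak_rate
  # the starting gains may already satisfy the probe
  res <- probe(1)
  if (feasible(res)) return(res)
  # The probe response ignites discontinuously as the gain scale grows
  # (recurrent amplification has a threshold), so the peak rate need not
  # pass through the band midpoint.  Bisect for the smallest scale whose
  # peak reaches the band, then walk upward if the network at the
  # ignition point has not yet become transient.
  lo <- 0.05; hi <- 1
  while (res$peak_rate < target_range[1] && hi < 64) {
    lo <- hi
    hi <- hi * 2
    res <- probe(hi)
  }
  if (res$peak_rate < target_range[1])
    stop("calibration failure: peak core rate ",
         signif(res$peak_rate, 3), " below ", target_range[1],
         " even at scale ", hi)
  for (i in seq_len(max_iter)) {
    sc <- (lo + hi) / 2
    cand <- probe(sc)
    if (cand$peak_rate < target_range[1]) {
      lo <- sc
    } else {
      hi <- sc
      res <- cand
    }
    if (feasible(cand)) return(cand)
  }
  for (sc in hi * c(1.05, 1.1, 1.2, 1.35, 1.5)) {
    cand <- probe(sc)
    if (feasible(cand)) return(cand)
  }
  if (res$peak_rate < target_range[1] || res$peak_rate > target_range[2])
    stop("calibration failure: peak core rate ", signif(res$peak_rate, 3),
         " outside [", target_range[1], ", ", target_range[2], "]")
  stop("calibration failure: activity ", signif(res$settle_rate, 3),
       " has not settled below ", settle_frac, " x peak within ",
       settle_ms, " ms of tone offset")
}

#' Steady-state response amplitude as a function of SOI
#'
#' Runs a repetitive single-tone train at each onset interval and reports
#' the response amplitude (peak absolute baseline-corrected MEG deflection
#' within 0-200 ms of onset) of the first tone and the steady state (mean
#' over the trailing tones).  With repetitive stimulation the response
#' grows with SOI: depression accumulates most at short intervals and the
#' response approaches the unadapted single-tone response once the SOI far
#' exceeds the recovery time constant.
#'
#' @param soi_list onset intervals, ms (ascending).
#' @param n_reps tones per train.
#' @param n_tail trailing tones averaged for the steady state.
#' @param connectome a `connectome`.
#' @param dynamics a `dynamics_params`.
#' @param meg a `meg_params`.
#' @param channel,duration,amplitude the repeated tone.
#' @return data.frame with columns `soi`, `first_amp`, `steady_amp`.
#' @export
repetition_suppression_curve <- function(soi_list = c(100, 500, 1000,
                                                      2000, 4000),
                                         n_reps = 20, n_tail = 5,
                                         connectome = NULL,
                                         dynamics = dynamics_params(),
                                         meg = meg_params(),
                                         channel = 7, duration = 50,
                                         amplitude = 1) {
  stopifnot(!is.unsorted(soi_list))
  if (is.null(connectome)) connectome <- build_connectome(default_anatomy())
  amp_of <- function(sig, onset_idx, dt) {
    base <- mean(sig[seq(max(1, onset_idx - 50), onset_idx)])
    win <- sig[onset_idx:min(length(sig), onset_idx + round(200 / dt))]
    max(abs(win - base))
  }
  rows <- lapply(soi_list, function(soi) {
    onsets <- (seq_len(n_reps) - 1) * soi
    sq <- data.frame(onset = onsets, duration = duration,
                     channel = channel, amplitude = amplitude,
                     condition = "tone", sequence_id = seq_len(n_reps))
    tr <- simulate_network(connectome, sq, params = dynamics, meg = meg)
    dt <- tr$dt
    amps <- vapply(onsets, function(o) amp_of(tr$meg, round(o / dt) + 1,
                                              dt), 0)
    data.frame(soi = soi, first_amp = amps[1],
               steady_amp = mean(utils::tail(amps, n_tail)))
  })
  do.call(rbind, rows)
}
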