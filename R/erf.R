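#' MEG read-out parameters
#'
#' The MEG proxy is the spatial sum of the excitatory input currents to the
#' excitatory populations, with each connection's contribution weighted by
#' its class: feedforward currents count -2, feedback and intra-field
#' currents +1.  By default only currents into cortical targets are summed
#' (the thalamus contributes little to MEG).
#'
#' @param class_weights named numeric with entries `feedforward`,
#'   `feedback`, `intra_field`.
#' @param include_thalamic_targets also sum currents into MGN units.
#' @return A list of class `meg_params`.
#' @export
meg_params <- function(class_weights = c(feedforward = -2, feedback = 1,
                                         intra_field = 1),
                       include_thalamic_targets = FALSE) {
  need <- c("feedforward", "feedback", "intra_field")
  class_weights <- class_weights[need]
  if (anyNA(class_weights) || !all(is.finite(class_weights)))
    stop("class_weights must give finite weights for ",
         paste(need, collapse = ", "))
  structure(list(class_weights = class_weights,
                 include_thalamic_targets = isTRUE(include_thalamic_targets)),
            class = "meg_params")
}

#' Aggregated MEG weight per presynaptic column
#'
#' Because every connection leaving column `j` carries the same current
#' `q_j g(u_j)`, the MEG sum collapses to `sum_j s_j q_j g(u_j)` with
#' `s_j = sum over retained W_ee entries out of j of class_weight * weight`.
#' This returns the vector `s`.
#'
#' @param connectome a `connectome`.
#' @param params a `meg_params`.
#' @return Numeric vector, one entry per unit.
#' @export
meg_presyn_weights <- function(connectome, params = meg_params()) {
  stopifnot(inherits(connectome, "connectome"))
  ent <- connectome$entries
  if (!all(ent$class %in% names(params$class_weights)))
    stop("connectome entries carry unknown class labels")
  keep <- if (params$include_thalamic_targets) rep(TRUE, nrow(ent))
          else connectome$units$cortical[ent$post]
  ent <- ent[keep, , drop = FALSE]
  w <- params$class_weights[ent$class] * ent$weight
  s <- numeric(nrow(connectome$units))
  agg <- tapply(w, ent$pre, sum)
  s[as.integer(names(agg))] <- as.numeric(agg)
  s
}

#' Recompute the MEG proxy from a recorded trajectory
#'
#' Reference implementation of the read-out: at each time step, the sum
#' over retained `W_ee` connections of class weight x connection weight x
#' presynaptic depressed firing rate `q g(u)`.  Requires a trajectory
#' recorded with `record_state = TRUE`; the compiled integrator produces
#' the identical series on the fly.
#'
#' @param trajectory a `trajectory` with recorded state.
#' @param connectome the `connectome` it was simulated with.
#' @param params a `meg_params`.
#' @return Numeric vector, one sample per trajectory time point.
#' @export
meg_signal <- function(trajectory, connectome, params = meg_params()) {
  stopifnot(inherits(trajectory, "trajectory"))
  if (is.null(trajectory$u))
    stop("trajectory has no recorded state; rerun with record_state = TRUE")
  if (ncol(trajectory$u) != nrow(connectome$units))
    stop("trajectory and connectome dimensions disagree")
  s <- meg_presyn_weights(connectome, params)
  gu <- firing_rate(trajectory$u, trajectory$params$theta)
  r <- if (trajectory$params$stsd) trajectory$q * gu else gu
  as.numeric(r %*% s)
}

.new_erf <- function(time, waveforms, n_epochs, n_dropped, processing) {
  structure(list(time = time, waveforms = waveforms, n_epochs = n_epochs,
                 n_dropped = n_dropped, processing = processing),
            class = "erf_result")
}

#' @export
print.erf_result <- function(x, ...) {
  cat("erf_result:", ncol(x$waveforms), "condition(s) over [",
      min(x$time), ",", max(x$time), "] ms\n")
  for (cn in colnames(x$waveforms))
    cat(sprintf("  %-20s n = %d\n", cn, x$n_epochs[[cn]]))
  cat("  processing:", paste(x$processing, collapse = " -> "), "\n")
  invisible(x)
}

#' Epoch a signal around stimulus events and average per condition
#'
#' Cuts fixed windows time-locked to event onsets (for omissions, the
#' expected onset of the omitted tone) and averages them per condition.
#' Epochs extending beyond the recording are dropped and counted.
#'
#' @param signal numeric vector sampled at `dt` ms, first sample at t = 0.
#' @param events a `stimulus_sequence` or event data.frame.
#' @param conditions conditions to average; default all present.
#' @param window epoch window relative to onset, ms.
#' @param dt sampling step of `signal`, ms.
#' @return An `erf_result` with one waveform column per condition.
#' @export
epoch_average <- function(signal, events, conditions = NULL,
                          window = c(-100, 400), dt = 1) {
  ev <- if (inherits(events, "stimulus_sequence")) events$events else events
  if (is.null(conditions)) conditions <- unique(ev$condition)
  rel <- seq(round(window[1] / dt), round(window[2] / dt))
  time <- rel * dt
  nt <- length(signal)
  waves <- matrix(NA_real_, length(rel), length(conditions),
                  dimnames = list(NULL, conditions))
  n_epochs <- n_dropped <- stats::setNames(integer(length(conditions)),
                                           conditions)
  for (cn in conditions) {
    idx0 <- round(ev$onset[ev$condition == cn] / dt)
    if (length(idx0) == 0)
      stop("no events with condition '", cn, "'")
    ok <- idx0 + rel[1] >= 0 & idx0 + rel[length(rel)] <= nt - 1
    n_dropped[[cn]] <- sum(!ok)
    idx0 <- idx0[ok]
    if (length(idx0) == 0)
      stop("all epochs for condition '", cn, "' fall outside the recording")
    epochs <- matrix(signal[outer(idx0, rel, "+") + 1L],
                     nrow = length(idx0))
    waves[, cn] <- colMeans(epochs)
    n_epochs[[cn]] <- length(idx0)
  }
  .new_erf(time, waves, as.list(n_epochs), as.list(n_dropped),
           sprintf("epoch_average(window = [%g, %g] ms)",
                   window[1], window[2]))
}

#' Baseline-correct averaged waveforms
#'
#' Subtracts from each condition's waveform its mean over the baseline
#' window (endpoints included).
#'
#' @param erf an `erf_result`.
#' @param baseline baseline window, ms.
#' @return The corrected `erf_result`.
#' @export
baseline_correct <- function(erf, baseline = c(-100, 0)) {
  stopifnot(inherits(erf, "erf_result"))
  sel <- erf$time >= baseline[1] & erf$time <= baseline[2]
  if (!any(sel)) stop("baseline window contains no samples")
  mu <- colMeans(erf$waveforms[sel, , drop = FALSE])
  erf$waveforms <- sweep(erf$waveforms, 2, mu)
  erf$processing <- c(erf$processing,
                      sprintf("baseline_correct([%g, %g] ms)",
                              baseline[1], baseline[2]))
  erf
}

# zero-phase 2nd-order Butterworth highpass with odd-reflection padding
.highpass_vector <- function(x, cutoff, fs) {
  bf <- signal::butter(2, cutoff / (fs / 2), type = "high")
  n <- length(x)
  p <- n - 1
  xp <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  y <- signal::filtfilt(bf, xp)
  y[(p + 1):(p + n)]
}

#' Highpass-filter averaged waveforms
#'
#' Applies a zero-phase (forward-backward) second-order Butterworth
#' highpass to each condition's waveform, with odd-reflection padding to
#' suppress edge transients.  Zero phase avoids latency distortion of the
#' peaks.
#'
#' @param erf an `erf_result`.
#' @param cutoff highpass cutoff, Hz.
#' @param fs sampling rate, Hz (1000 / dt for the default 1-ms step).
#' @return The filtered `erf_result`.
#' @export
highpass_erf <- function(erf, cutoff = 1, fs = 1000) {
  stopifnot(inherits(erf, "erf_result"))
  if (fs <= 2 * cutoff) stop("sampling rate must exceed twice the cutoff")
  if (nrow(erf$waveforms) < 8) stop("epoch too short to filter")
  erf$waveforms <- apply(erf$waveforms, 2, .highpass_vector,
                         cutoff = cutoff, fs = fs)
  erf$processing <- c(erf$processing,
                      sprintf("highpass(%g Hz, zero-phase order-2)", cutoff))
  erf
}

#' Peak metric of one condition's waveform
#'
#' The extremum of the absolute waveform within the search window; the
#' returned amplitude keeps its sign.
#'
#' @param erf an `erf_result`.
#' @param condition condition name.
#' @param search search window, ms.
#' @return list with `amplitude` (signed), `abs_amplitude` and `latency`
#'   (ms).
#' @export
peak_metric <- function(erf, condition, search = c(50, 350)) {
  stopifnot(inherits(erf, "erf_result"))
  if (!condition %in% colnames(erf$waveforms))
    stop("no waveform for condition '", condition, "'")
  sel <- erf$time >= search[1] & erf$time <= search[2]
  if (!any(sel)) stop("search window outside the epoch")
  w <- erf$waveforms[sel, condition]
  tt <- erf$time[sel]
  i <- which.max(abs(w))
  list(amplitude = w[i], abs_amplitude = abs(w[i]), latency = tt[i])
}

#' Difference wave and mismatch-response metrics
#'
#' Computes deviant-minus-standard and locates the extremum of its
#' absolute value within the search window.
#'
#' @param erf an `erf_result` containing both conditions.
#' @param deviant,standard condition names.
#' @param search search window, ms.
#' @return list with `time`, `difference`, `peak_amplitude` (signed),
#'   `peak_abs_amplitude`, `peak_latency`, and per-condition peaks.
#' @export
mmn_metrics <- function(erf, deviant = "deviant", standard = "standard",
                        search = c(50, 350)) {
  stopifnot(inherits(erf, "erf_result"))
  for (cn in c(deviant, standard))
    if (!cn %in% colnames(erf$waveforms))
      stop("no waveform for condition '", cn, "'")
  diffw <- erf$waveforms[, deviant] - erf$waveforms[, standard]
  sel <- erf$time >= search[1] & erf$time <= search[2]
  if (!any(sel)) stop("search window outside the epoch")
  w <- diffw[sel]; tt <- erf$time[sel]
  i <- which.max(abs(w))
  list(time = erf$time, difference = diffw,
       peak_amplitude = w[i], peak_abs_amplitude = abs(w[i]),
       peak_latency = tt[i],
       deviant_peak = peak_metric(erf, deviant, search),
       standard_peak = peak_metric(erf, standard, search))
}

#' Export an ERF result to CSV (with a JSON metrics sidecar)
#'
#' @param erf an `erf_result`.
#' @param path output CSV path; columns `time_ms` plus one per condition.
#' @param metrics optional list (e.g. from [mmn_metrics()]) written to
#'   `<path>.json` together with epoch counts and the processing record.
#' @return `path`, invisibly.
#' @export
write_erf <- function(erf, path, metrics = NULL) {
  stopifnot(inherits(erf, "erf_result"))
  tab <- data.frame(time_ms = erf$time, erf$waveforms,
                    check.names = FALSE)
  utils::write.csv(tab, path, row.names = FALSE)
  side <- list(n_epochs = erf$n_epochs, n_dropped = erf$n_dropped,
               processing = erf$processing)
  if (!is.null(metrics))
    side$metrics <- metrics[setdiff(names(metrics),
                                    c("time", "difference"))]
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
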