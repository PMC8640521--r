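#' @name stimuli
#' @title Stimulus protocol generators
#' @description
#' Each generator returns a `stimulus_sequence`: a seeded, time-ordered
#' event table of tones (and omissions) on the 16 abstract tonotopic
#' channels, plus protocol metadata.  Identical seed and parameters yield
#' byte-identical tables.  Omission events are real rows with zero
#' amplitude carrying the expected onset and channel of the omitted tone,
#' so that epochs can be locked to them.
NULL

# run expr with a local RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

.new_sequence <- function(events, paradigm, params, seed) {
  events <- events[order(events$onset), , drop = FALSE]
  events$channel <- as.integer(events$channel)
  events$sequence_id <- as.integer(events$sequence_id)
  rownames(events) <- NULL
  events$paradigm <- paradigm
  total <- if (nrow(events)) max(events$onset + events$duration) else 0
  structure(list(events = events, total_duration = total,
                 seed = seed, paradigm = paradigm, params = params),
            class = "stimulus_sequence")
}

#' @export
print.stimulus_sequence <- function(x, ...) {
  cat("stimulus_sequence '", x$paradigm, "': ", nrow(x$events),
      " events over ", round(x$total_duration / 1000, 1), " s (seed ",
      x$seed, ")\n", sep = "")
  print(table(x$events$condition))
  invisible(x)
}

# forbid deviants closer than min_separation positions (0 = unconstrained)
.apply_min_separation <- function(is_dev, min_separation) {
  if (min_separation < 1) return(is_dev)
  last <- -Inf
  for (i in seq_along(is_dev)) {
    if (is_dev[i]) {
      if (i - last <= min_separation) is_dev[i] <- FALSE else last <- i
    }
  }
  is_dev
}

#' Omission paradigm: isochronous tones with random omissions
#'
#' Tones on a fixed onset-to-onset grid, each slot independently omitted
#' with probability `p_omit`; omissions are the deviants.
#'
#' @param n_slots number of grid slots.
#' @param soi stimulus onset interval (onset-to-onset), ms.
#' @param p_omit omission probability per slot.
#' @param channel tonotopic channel of the tone.
#' @param duration tone duration, ms.
#' @param amplitude tone amplitude, afferent input units.
#' @param min_separation if > 0, forbid deviants within this many slots of
#'   the previous deviant (default unconstrained).
#' @param seed RNG seed.
#' @return A `stimulus_sequence` with conditions `standard` / `deviant`.
#' @export
make_omission <- function(n_slots, soi = 100, p_omit = 0.10, channel = 7,
                          duration = 50, amplitude = 1, min_separation = 0,
                          seed = 1) {
  stopifnot(p_omit >= 0, p_omit < 1, n_slots >= 1)
  omit <- .with_seed(seed,
    .apply_min_separation(stats::runif(n_slots) < p_omit, min_separation))
  ev <- data.frame(
    onset = (seq_len(n_slots) - 1) * soi,
    duration = duration,
    channel = channel,
    amplitude = ifelse(omit, 0, amplitude),
    condition = ifelse(omit, "deviant", "standard"),
    sequence_id = seq_len(n_slots),
    stringsAsFactors = FALSE
  )
  .new_sequence(ev, "omission",
                list(n_slots = n_slots, soi = soi, p_omit = p_omit,
                     channel = channel, duration = duration,
                     amplitude = amplitude,
                     min_separation = min_separation), seed)
}

#' Alternation paradigm with unexpected repetitions
#'
#' The base sequence alternates between two channels (low, high, low, ...).
#' Each scheduled high-channel tone is replaced, with probability
#' `p_repeat`, by a repetition of the low-channel tone; these repeated
#' low tones are the deviants and the regularly alternating low tones are
#' the standards.  High-channel tones keep the tag `alternate`.
#'
#' @param n_tones total number of tones.
#' @param soi onset-to-onset interval, ms.
#' @param channels length-2 integer vector `(low, high)`.
#' @param p_repeat replacement probability per scheduled high tone.
#' @inheritParams make_omission
#' @return A `stimulus_sequence` with conditions `standard` / `deviant` /
#'   `alternate`.
#' @export
make_alternating <- function(n_tones, soi = 500, channels = c(6, 9),
                             p_repeat = 0.05, duration = 50, amplitude = 1,
                             min_separation = 0, seed = 1) {
  stopifnot(length(channels) == 2, p_repeat >= 0, p_repeat < 1)
  scheduled <- rep(channels, length.out = n_tones)
  high_pos <- which(scheduled == channels[2])
  rep_here <- .with_seed(seed,
    .apply_min_separation(stats::runif(length(high_pos)) < p_repeat,
                          min_separation))
  chan <- scheduled
  chan[high_pos[rep_here]] <- channels[1]
  cond <- ifelse(scheduled == channels[1], "standard", "alternate")
  cond[high_pos[rep_here]] <- "deviant"
  ev <- data.frame(
    onset = (seq_len(n_tones) - 1) * soi,
    duration = duration, channel = chan, amplitude = amplitude,
    condition = cond, sequence_id = seq_len(n_tones),
    stringsAsFactors = FALSE
  )
  .new_sequence(ev, "alternating",
                list(n_tones = n_tones, soi = soi, channels = channels,
                     p_repeat = p_repeat, duration = duration,
                     amplitude = amplitude,
                     min_separation = min_separation), seed)
}

#' Local-global paradigm: five-tone sequences with local and global deviance
#'
#' Emits tone quintets `xxxxX` (five tones at `x_channel`) and `xxxxY`
#' (fifth tone at `y_channel`), plus occasional four-tone `xxxx` sequences,
#' with probabilities `p` = (standard, deviant, short).  `roles` selects
#' which quintet type is the within-block (global) standard; the other is
#' the global deviant.  Fifth tones carry conditions of the form
#' `"X_global_deviant"`, `"Y_global_standard"`, etc.; earlier tones are
#' tagged `context`.
#'
#' @param n_sequences number of sequences in the block.
#' @param soa within-sequence onset asynchrony, ms.
#' @param gap silent period from last tone offset to next sequence onset, ms.
#' @param x_channel,y_channel tonotopic channels of the repeated tone and
#'   the local deviant.
#' @param roles which sequence type (`"xxxxX"` or `"xxxxY"`) is the global
#'   standard.
#' @param p probabilities of (global standard, global deviant, four-tone)
#'   sequences; must sum to 1.
#' @inheritParams make_omission
#' @return A `stimulus_sequence`.
#' @export
make_local_global <- function(n_sequences, soa = 150, gap = 850,
                              x_channel = 5, y_channel = 12,
                              duration = 50,
                              roles = c("xxxxY", "xxxxX"),
                              p = c(0.75, 0.15, 0.10),
                              amplitude = 1, seed = 1) {
  standard_type <- match.arg(roles)
  stopifnot(length(p) == 3, all(p >= 0), all(p <= 1),
            abs(sum(p) - 1) < 1e-9)
  deviant_type <- setdiff(c("xxxxX", "xxxxY"), standard_type)
  types <- .with_seed(seed,
    sample(c(standard_type, deviant_type, "xxxx"), n_sequences,
           replace = TRUE, prob = p))
  rows <- vector("list", n_sequences)
  t0 <- 0
  for (s in seq_len(n_sequences)) {
    ty <- types[s]
    k <- if (ty == "xxxx") 4L else 5L
    chan <- rep(x_channel, k)
    if (ty == "xxxxY") chan[5] <- y_channel
    cond <- rep("context", k)
    if (k == 5L) {
      role <- if (ty == standard_type) "global_standard" else
        "global_deviant"
      cond[5] <- paste0(if (ty == "xxxxX") "X" else "Y", "_", role)
    }
    rows[[s]] <- data.frame(
      onset = t0 + (seq_len(k) - 1) * soa,
      duration = duration, channel = chan, amplitude = amplitude,
      condition = cond, sequence_id = s, stringsAsFactors = FALSE
    )
    t0 <- t0 + (k - 1) * soa + duration + gap
  }
  .new_sequence(do.call(rbind, rows), "local_global",
                list(n_sequences = n_sequences, soa = soa, gap = gap,
                     x_channel = x_channel, y_channel = y_channel,
                     duration = duration, roles = standard_type, p = p,
                     amplitude = amplitude), seed)
}

#' Classic oddball paradigm
#'
#' Isochronous tones; each position is independently a deviant (different
#' channel) with probability `p_dev`.
#'
#' @param n_tones number of tones.
#' @param soi onset-to-onset interval, ms.
#' @param std_channel,dev_channel tonotopic channels of standard and
#'   deviant.
#' @param p_dev deviant probability.
#' @inheritParams make_omission
#' @return A `stimulus_sequence` with conditions `standard` / `deviant`.
#' @export
make_oddball <- function(n_tones, soi = 500, std_channel = 9,
                         dev_channel = 10, p_dev = 0.10, duration = 50,
                         amplitude = 1, min_separation = 0, seed = 1) {
  stopifnot(std_channel != dev_channel, p_dev >= 0, p_dev <= 1)
  dev <- .with_seed(seed,
    .apply_min_separation(stats::runif(n_tones) < p_dev, min_separation))
  ev <- data.frame(
    onset = (seq_len(n_tones) - 1) * soi,
    duration = duration,
    channel = ifelse(dev, dev_channel, std_channel),
    amplitude = amplitude,
    condition = ifelse(dev, "deviant", "standard"),
    sequence_id = seq_len(n_tones), stringsAsFactors = FALSE
  )
  .new_sequence(ev, "oddball",
                list(n_tones = n_tones, soi = soi,
                     std_channel = std_channel, dev_channel = dev_channel,
                     p_dev = p_dev, duration = duration,
                     amplitude = amplitude,
                     min_separation = min_separation), seed)
}

#' Multi-standard (equiprobable) control paradigm
#'
#' Each position draws its channel uniformly from `channels`, so every tone
#' -- including the one matching the oddball deviant -- occurs at the same
#' rate.  Tones on `control_channel` are tagged `control` for comparison
#' with the oddball deviant; all others are tagged `filler`.
#'
#' @param channels candidate channels (each drawn with equal probability).
#' @param control_channel the channel compared against the oddball deviant.
#' @inheritParams make_oddball
#' @return A `stimulus_sequence` with conditions `control` / `filler`.
#' @export
make_multistandard <- function(n_tones, soi = 500, channels = 4:13,
                               control_channel = 10, duration = 50,
                               amplitude = 1, seed = 1) {
  stopifnot(length(channels) >= 2, control_channel %in% channels)
  chan <- .with_seed(seed, sample(channels, n_tones, replace = TRUE))
  ev <- data.frame(
    onset = (seq_len(n_tones) - 1) * soi,
    duration = duration, channel = chan, amplitude = amplitude,
    condition = ifelse(chan == control_channel, "control", "filler"),
    sequence_id = seq_len(n_tones), stringsAsFactors = FALSE
  )
  .new_sequence(ev, "multistandard",
                list(n_tones = n_tones, soi = soi, channels = channels,
                     control_channel = control_channel,
                     duration = duration, amplitude = amplitude), seed)
}

#' Anisochronous oddball paradigm
#'
#' Oddball stimulation in which the silent interval between consecutive
#' tone offset and the next onset is drawn uniformly from `gap_range`.
#'
#' @param gap_range length-2 numeric, min/max silent gap in ms.
#' @inheritParams make_oddball
#' @return A `stimulus_sequence` with conditions `standard` / `deviant`.
#' @export
make_anisochronous <- function(n_tones, duration = 300,
                               gap_range = c(200, 1000), std_channel = 6,
                               dev_channel = 9, p_dev = 0.20,
                               amplitude = 1, min_separation = 0,
                               seed = 1) {
  stopifnot(length(gap_range) == 2, gap_range[1] < gap_range[2],
            std_channel != dev_channel)
  draws <- .with_seed(seed, list(
    dev = .apply_min_separation(stats::runif(n_tones) < p_dev,
                                min_separation),
    gaps = stats::runif(n_tones - 1, gap_range[1], gap_range[2])))
  dev <- draws$dev
  gaps <- draws$gaps
  onset <- cumsum(c(0, duration + gaps))
  ev <- data.frame(
    onset = onset, duration = duration,
    channel = ifelse(dev, dev_channel, std_channel),
    amplitude = amplitude,
    condition = ifelse(dev, "deviant", "standard"),
    sequence_id = seq_len(n_tones), stringsAsFactors = FALSE
  )
  .new_sequence(ev, "anisochronous",
                list(n_tones = n_tones, duration = duration,
                     gap_range = gap_range, std_channel = std_channel,
                     dev_channel = dev_channel, p_dev = p_dev,
                     amplitude = amplitude,
                     min_separation = min_separation), seed)
}

#' Afferent input vector at a time point
#'
#' Evaluates the tonotopic afferent drive of a stimulus sequence at time
#' `t`: each active tone contributes a rectangular envelope with linear
#' on/off ramps of `ramp` ms at its channel; omissions (zero-amplitude
#' events) contribute nothing.  This is the same envelope the compiled
#' integrator applies internally.
#'
#' @param sequence a `stimulus_sequence` or event data.frame.
#' @param t time, ms.
#' @param n_channels length of the returned vector.
#' @param ramp ramp duration, ms.
#' @return Numeric vector of length `n_channels`.
#' @export
afferent_input <- function(sequence, t, n_channels = 16, ramp = 5) {
  events <- if (inherits(sequence, "stimulus_sequence")) sequence$events
            else sequence
  out <- numeric(n_channels)
  s <- t - events$onset
  act <- which(s >= 0 & s < events$duration & events$amplitude > 0)
  for (i in act) {
    env <- if (ramp > 0)
      max(0, min(1, s[i] / ramp, (events$duration[i] - s[i]) / ramp))
    else 1
    out[events$channel[i]] <- out[events$channel[i]] +
      events$amplitude[i] * env
  }
  out
}

#' Write a stimulus sequence to TSV (with a JSON sidecar)
#'
#' The event table goes to `<path>` as tab-separated text with columns
#' onset_ms, duration_ms, channel, amplitude, condition, sequence_id,
#' paradigm; seed and generator parameters go to `<path>.json`.
#'
#' @param sequence a `stimulus_sequence`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(sequence, path) {
  stopifnot(inherits(sequence, "stimulus_sequence"))
  ev <- sequence$events
  out <- data.frame(
    onset_ms = sprintf("%.17g", ev$onset),
    duration_ms = sprintf("%.17g", ev$duration),
    channel = ev$channel,
    amplitude = sprintf("%.17g", ev$amplitude),
    condition = ev$condition,
    sequence_id = ev$sequence_id,
    paradigm = ev$paradigm, stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(paradigm = sequence$paradigm,
                            seed = sequence$seed,
                            params = sequence$params),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a stimulus sequence written by [write_events()]
#'
#' @param path TSV path (the `.json` sidecar must sit next to it).
#' @return A `stimulus_sequence`.
#' @export
read_events <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  ev <- data.frame(
    onset = as.numeric(tab$onset_ms),
    duration = as.numeric(tab$duration_ms),
    channel = as.integer(tab$channel),
    amplitude = as.numeric(tab$amplitude),
    condition = tab$condition,
    sequence_id = as.integer(tab$sequence_id),
    stringsAsFactors = FALSE
  )
  .new_sequence(ev, meta$paradigm, meta$params, meta$seed)
}
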