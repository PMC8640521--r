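test_that("MEG weights collapse correctly onto presynaptic columns", {
  # 3-unit chain MGN -> core X -> belt Y with single-column fields
  an <- new_anatomy(
    fields = data.frame(name = c("X", "Y", "MGN"),
                        level = c("core", "belt", "thalamus"),
                        n_columns = 1L),
    edges = data.frame(from = c("MGN", "X", "X", "Y"),
                       to = c("X", "MGN", "Y", "X"),
                       class = c("feedforward", "feedback",
                                 "feedforward", "feedback")))
  cp <- connectivity_params(
    gain_ff = c(thalamocortical = 0.7, core_belt = 0.4, belt_parabelt = 0),
    fb_ratio = 0.5,
    sigma = c(thalamocortical = 0.1, core_belt = 0.1, belt_parabelt = 0.1),
    w_self = 0.3, lat_exc = 0, gain_ie = 0, sigma_ie = 1, ie_span = 0L,
    w_ei = 0)
  con <- build_connectome(an, cp)
  s <- meg_presyn_weights(con)     # units: X, Y, MGN
  # X sends: self 0.3 (intra, +1), ff X->Y 0.4 (-2), fb X->MGN (thalamic
  # target, excluded)
  expect_equal(s[1], 1 * 0.3 - 2 * 0.4)
  # Y sends: self 0.3 (+1), fb Y->X 0.2 (+1)
  expect_equal(s[2], 0.3 + 0.2)
  # MGN sends: ff MGN->X 0.7 (-2); its self-feedback targets the thalamus
  expect_equal(s[3], -2 * 0.7)
  s_all <- meg_presyn_weights(con, meg_params(include_thalamic_targets =
                                                TRUE))
  expect_equal(s_all[1], 0.3 - 2 * 0.4 + 1 * 0.35)
  expect_equal(s_all[3], -2 * 0.7 + 0.3)

  # hand-computed MEG for constant rates
  u <- c(0.8, 0.4, 1.2); q <- c(0.9, 1, 0.5)
  traj <- structure(list(u = matrix(u, 1), q = matrix(q, 1),
                         params = dynamics_params(), times = 0),
                    class = "trajectory")
  expect_equal(meg_signal(traj, con),
               sum(s * q * firing_rate(u)))
})

test_that("the compiled MEG read-out equals the reference implementation", {
  con <- default_con()
  sq <- make_oddball(6, soi = 150, seed = 2)
  tr <- simulate_network(con, sq, duration = 1400, record_state = TRUE)
  expect_equal(tr$meg, meg_signal(tr, con), tolerance = 1e-12)
  expect_gt(max(abs(tr$meg)), 0)
  # knockout read-out equals setting q = 1 in the formula
  trk <- simulate_network(con, sq, duration = 1400, record_state = TRUE,
                          params = knockout_stsd(dynamics_params()))
  s <- meg_presyn_weights(con)
  expect_equal(trk$meg,
               as.numeric(firing_rate(trk$u) %*% s), tolerance = 1e-12)
})

test_that("epoch averaging reproduces templates and drops edge epochs", {
  tpl <- sin(seq(0, 3 * pi, length.out = 501))
  onsets <- seq(500, 9500, by = 1000)
  sig <- numeric(10500)
  for (o in onsets) sig[o + (-100:400) + 1] <- sig[o + (-100:400) + 1] + tpl
  ev <- data.frame(onset = c(50, onsets), duration = 50, channel = 1,
                   amplitude = 1, condition = "a", sequence_id = 1)
  erf <- epoch_average(sig, ev, window = c(-100, 400))
  expect_equal(erf$n_epochs$a, length(onsets))
  expect_equal(erf$n_dropped$a, 1)   # the onset-50 epoch starts before 0
  expect_equal(unname(erf$waveforms[, "a"]), tpl, tolerance = 1e-12)

  # two epochs of +x and -x average to zero
  sig2 <- c(rep(0, 100), tpl, rep(0, 600), -tpl, rep(0, 600))
  ev2 <- data.frame(onset = c(200, 1301), duration = 1, channel = 1,
                    amplitude = 1, condition = "b", sequence_id = 1)
  erf2 <- epoch_average(sig2, ev2, window = c(-50, 300))
  expect_equal(max(abs(erf2$waveforms)), 0)
  expect_error(epoch_average(sig2, ev2, conditions = "missing"),
               "missing")
})

test_that("averaging a noisy template converges at the expected rate", {
  set.seed(99)
  tpl <- exp(-((seq(-100, 400)) - 120)^2 / 2500)
  n_ep <- 400
  sd_noise <- 0.5
  onsets <- seq(200, by = 600, length.out = n_ep)
  sig <- stats::rnorm(onsets[n_ep] + 600, sd = sd_noise)
  for (o in onsets) sig[o + (-100:400) + 1] <- sig[o + (-100:400) + 1] + tpl
  ev <- data.frame(onset = onsets, duration = 50, channel = 1,
                   amplitude = 1, condition = "t", sequence_id = 1)
  erf <- epoch_average(sig, ev, window = c(-100, 400))
  se <- sd_noise / sqrt(n_ep)
  dev <- abs(erf$waveforms[, "t"] - tpl)
  # pointwise-normal error: nearly all samples within 3 s.e., none far out
  expect_gt(mean(dev < 3 * se), 0.985)
  expect_lt(max(dev), 5.5 * se)
})

test_that("baseline correction subtracts the baseline-window mean", {
  t_ax <- seq(-100, 400)
  erf <- epoch_average(rep(3.5, 2000),
                       data.frame(onset = c(500, 1200), duration = 1,
                                  channel = 1, amplitude = 1,
                                  condition = "c", sequence_id = 1),
                       window = c(-100, 400))
  bc <- baseline_correct(erf)
  expect_equal(max(abs(bc$waveforms)), 0)

  # ramp t -> t is shifted up by +50 (mean of the ramp over [-100, 0])
  ramp_erf <- structure(list(time = t_ax,
                             waveforms = matrix(t_ax, ncol = 1,
                                                dimnames = list(NULL, "r")),
                             n_epochs = list(r = 1),
                             n_dropped = list(r = 0), processing = "x"),
                        class = "erf_result")
  bc2 <- baseline_correct(ramp_erf, c(-100, 0))
  expect_equal(unname(bc2$waveforms[, "r"]), t_ax + 50)
  # already zero-mean baseline: unchanged
  expect_equal(baseline_correct(bc2, c(-100, 0))$waveforms,
               bc2$waveforms)
})

test_that("the highpass filter removes DC and passes the signal band", {
  t_ax <- seq(0, 10000)
  mk_erf <- function(x) structure(
    list(time = t_ax, waveforms = matrix(x, ncol = 1,
                                         dimnames = list(NULL, "w")),
         n_epochs = list(w = 1), n_dropped = list(w = 0),
         processing = character()),
    class = "erf_result")
  mid <- t_ax > 2000 & t_ax < 8000
  # DC: attenuated by more than 40 dB
  hp <- highpass_erf(mk_erf(rep(2, length(t_ax))))
  expect_lt(max(abs(hp$waveforms[mid, 1])), 2 * 0.01)
  # 20 Hz: preserved within 5%
  s20 <- sin(2 * pi * 20 * t_ax / 1000)
  hp20 <- highpass_erf(mk_erf(s20))
  expect_lt(max(abs(hp20$waveforms[mid, 1] - s20[mid])), 0.05)
  # 0.1 Hz: attenuated by more than 90%
  s01 <- sin(2 * pi * 0.1 * t_ax / 1000)
  hp01 <- highpass_erf(mk_erf(s01))
  expect_lt(max(abs(hp01$waveforms[mid, 1])), 0.1)
  expect_error(highpass_erf(mk_erf(rep(0, length(t_ax))), cutoff = 600),
               "sampling rate")
})

test_that("difference-wave metrics locate the analytic extremum", {
  t_ax <- seq(-100, 400)
  g1 <- 2 * exp(-(t_ax - 150)^2 / 2000)
  g2 <- 5 * exp(-(t_ax - 150)^2 / 2000)
  erf <- structure(list(
    time = t_ax,
    waveforms = cbind(standard = g1, deviant = g2),
    n_epochs = list(standard = 1, deviant = 1),
    n_dropped = list(standard = 0, deviant = 0),
    processing = character()), class = "erf_result")
  m <- mmn_metrics(erf)
  expect_equal(m$peak_amplitude, 3)      # (5 - 2) at the mode
  expect_equal(m$peak_latency, 150)
  expect_equal(m$deviant_peak$amplitude, 5)
  expect_equal(m$standard_peak$latency, 150)
  # identical waveforms: zero difference
  erf$waveforms[, "deviant"] <- g1
  m0 <- mmn_metrics(erf)
  expect_equal(m0$peak_abs_amplitude, 0)
  expect_error(mmn_metrics(erf, search = c(900, 1000)), "search window")
})

test_that("epoching and baseline correction commute with scaling", {
  set.seed(7)
  sig <- stats::rnorm(5000)
  ev <- data.frame(onset = c(600, 1600, 2600, 3600), duration = 50,
                   channel = 1, amplitude = 1, condition = "z",
                   sequence_id = 1)
  e1 <- baseline_correct(epoch_average(3 * sig, ev))
  e2 <- baseline_correct(epoch_average(sig, ev))
  expect_equal(e1$waveforms, 3 * e2$waveforms)
})

test_that("ERF results export to CSV with a metrics sidecar", {
  t_ax <- seq(-100, 400)
  erf <- structure(list(
    time = t_ax,
    waveforms = cbind(standard = sin(t_ax / 50),
                      deviant = cos(t_ax / 50)),
    n_epochs = list(standard = 10, deviant = 5),
    n_dropped = list(standard = 0, deviant = 1),
    processing = "epoch_average"), class = "erf_result")
  path <- withr::local_tempfile(fileext = ".csv")
  write_erf(erf, path, metrics = mmn_metrics(erf))
  tab <- utils::read.csv(path)
  expect_equal(names(tab), c("time_ms", "standard", "deviant"))
  expect_equal(tab$deviant, unname(erf$waveforms[, "deviant"]))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(side$n_epochs$deviant, 5)
  expect_true(is.numeric(side$metrics$peak_amplitude))
})
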