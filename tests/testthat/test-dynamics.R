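test_that("firing rate is thresholded and saturating", {
  expect_equal(firing_rate(0.05, 0.05), 0)
  expect_equal(firing_rate(-1, 0.05), 0)
  expect_equal(firing_rate(1.55, 0.05), tanh(1))
  x <- seq(-2, 10, by = 0.01)   # physiological membrane-potential range
  g <- firing_rate(x)
  expect_true(all(g >= 0 & g < 1))
  expect_true(all(diff(g) >= 0))
})

test_that("rest is a fixed point of the drift", {
  con <- default_con()
  n <- nrow(con$units)
  d <- drift(list(u = rep(0, n), v = rep(0, n), q = rep(1, n)),
             rep(0, n), con)
  expect_equal(d$du, rep(0, n))
  expect_equal(d$dv, rep(0, n))
  expect_equal(d$dq, rep(0, n))
})

test_that("an isolated leaky unit converges to its input", {
  con <- build_connectome(toy_anatomy(), connectivity_params(
    gain_ff = c(thalamocortical = 0, core_belt = 0, belt_parabelt = 0),
    sigma = c(thalamocortical = 0.1, core_belt = 0.1, belt_parabelt = 0.1),
    w_self = 0, lat_exc = 0, gain_ie = 0, sigma_ie = 1, ie_span = 0L,
    w_ei = 0))
  tone <- probe_tone(channel = 1, duration = 2000, amplitude = 0.8)
  tr <- simulate_network(con, tone, duration = 2000, warmup = 0,
                         record_state = TRUE, ramp = 0)
  mgn_col <- which(!con$units$cortical)
  expect_equal(tr$u[2000, mgn_col], 0.8, tolerance = 1e-3)
})

test_that("efficacy equilibrium under constant firing matches closed form", {
  con <- toy_connectome()
  n <- nrow(con$units)
  p <- dynamics_params(tau_rec = 1.2)
  for (cc in c(0.2, 0.5, 0.9)) {
    u_at <- 0.05 + 1.5 * atanh(cc)   # g(u) = cc
    tau_o <- ifelse(con$units$cortical, 100, 20)
    qstar <- tau_o / (tau_o + cc * p$tau_rec * 1000)
    d <- drift(list(u = rep(u_at, n), v = rep(0, n), q = qstar),
               rep(0, n), con, p)
    expect_equal(d$dq, rep(0, n), tolerance = 1e-12)
  }
})

test_that("silence from rest stays exactly at rest", {
  con <- default_con()
  tr <- simulate_network(con, NULL, duration = 1000, warmup = 500,
                         record_state = TRUE)
  expect_true(all(tr$u == 0))
  expect_true(all(tr$v == 0))
  expect_true(all(tr$q == 1))
  expect_true(all(tr$meg == 0))
})

test_that("efficacy recovery from a depressed start follows the closed form", {
  con <- toy_connectome()
  n <- nrow(con$units)
  p <- dynamics_params(tau_rec = 1.2)
  tr <- simulate_network(con, NULL, duration = 1201, warmup = 0, params = p,
                         record_state = TRUE,
                         init = list(u = rep(0, n), v = rep(0, n),
                                     q = rep(0.5, n)))
  # q(t) = 1 - 0.5 exp(-t / tau_rec); at t = tau_rec: ~0.81606
  expect_equal(tr$q[1201, 1], 1 - 0.5 * exp(-1), tolerance = 1e-3)
  tt <- c(100, 400, 800, 1200)
  expect_equal(tr$q[tt + 1, 1], 1 - 0.5 * exp(-tt / 1200), tolerance = 1e-3)
})

test_that("Euler trajectories match an adaptive-step reference integration", {
  skip_if_not_installed("deSolve")
  con <- toy_connectome(w_self = 0.4, gain_tc = 1.2, gain_ie = 0.8,
                        w_ei = 0.8)
  n <- nrow(con$units)
  p <- dynamics_params(tau_rec = 1.2, dt = 0.02)
  tone <- probe_tone(channel = 1, duration = 50, amplitude = 1)
  tr <- simulate_network(con, tone, duration = 400, warmup = 0,
                         record_state = TRUE, params = p)
  rhs <- function(t, y, parms) {
    st <- list(u = y[1:n], v = y[n + (1:n)], q = y[2 * n + (1:n)])
    input <- afferent_input(tone, t, n_channels = 1)
    inp <- numeric(n)
    inp[!con$units$cortical] <- input
    d <- drift(st, inp, con, p)
    list(c(d$du, d$dv, d$dq))
  }
  ref <- deSolve::lsoda(c(rep(0, 2 * n), rep(1, n)), times = tr$times, rhs,
                        parms = NULL, rtol = 1e-10, atol = 1e-12)
  for (i in 1:n) {
    scale <- max(abs(ref[, 1 + i]))
    expect_lt(max(abs(tr$u[, i] - ref[, 1 + i])) / scale, 1e-3)
    expect_lt(max(abs(tr$q[, i] - ref[, 1 + 2 * n + i])), 1e-3)
  }
})

test_that("halving the step changes a single-tone core response by < 5%", {
  con <- default_con()
  peaks <- vapply(c(1, 0.5), function(dt) {
    tr <- simulate_network(con, probe_tone(), duration = 500,
                           params = dynamics_params(dt = dt), warmup = 200)
    max(abs(tr$meg))
  }, 0)
  expect_lt(abs(peaks[1] - peaks[2]) / peaks[2], 0.05)
})

test_that("step sizes beyond the stability bound are rejected", {
  expect_error(dynamics_params(dt = 4), "tau_m / 10")
  expect_error(dynamics_params(tau_rec = 0), "positive")
})

test_that("state/connectome dimension mismatches are caught", {
  con <- default_con()
  expect_error(drift(list(u = 0, v = 0, q = 1), 0, con), "224")
  expect_error(simulate_network(con, probe_tone(channel = 20),
                                duration = 100), "1..16")
})

test_that("a non-finite state aborts with a diagnostic", {
  con <- toy_connectome()
  n <- nrow(con$units)
  expect_error(
    simulate_network(con, NULL, duration = 10, warmup = 0,
                     init = list(u = rep(NaN, n), v = rep(0, n),
                                 q = rep(1, n))),
    "non-finite state at unit 1")
})

test_that("STSD knockout pins the efficacies at one", {
  con <- default_con()
  p <- knockout_stsd(dynamics_params(tau_rec = 1.7))
  expect_false(p$stsd)
  tr <- simulate_network(con, make_oddball(20, seed = 3), params = p,
                         record_state = TRUE)
  expect_true(all(tr$q == 1))
  expect_equal(tr$q_range, c(1, 1))
})

test_that("knockout changes the first-ever response only via within-tone
           depression", {
  con <- default_con()
  tone <- probe_tone()
  tr1 <- simulate_network(con, tone, duration = 400)
  tr2 <- simulate_network(con, tone, duration = 400,
                          params = knockout_stsd(dynamics_params()))
  p1 <- max(abs(tr1$meg))
  p2 <- max(abs(tr2$meg))
  expect_gt(min(p1, p2), 0)
  # depression can only have reduced the read-out, and by no more than the
  # efficacy drop accrued during the tone itself
  expect_gt(p2, 0.95 * p1)
  expect_lt(abs(p1 - p2) / p2, (1 - tr1$q_range[1]) + 0.05)
})

test_that("efficacies stay in [0, 1] and recover monotonically after offset", {
  con <- default_con()
  sq <- make_oddball(8, soi = 120, seed = 7)
  tr <- simulate_network(con, sq, duration = 2500, record_state = TRUE)
  expect_gte(tr$q_range[1], 0)
  expect_lte(tr$q_range[2], 1)
  expect_lt(tr$g_max, 1)
  # after the last tone the cortex falls silent and every q is non-decreasing
  quiet <- which(tr$times > max(sq$events$onset) + 400)
  dq <- apply(tr$q[quiet, ], 2, diff)
  expect_true(all(dq >= -1e-12))
})

test_that("the compiled afferent input matches the reference envelope", {
  con <- default_con()
  sq <- make_omission(12, soi = 100, p_omit = 0.3, seed = 5)
  tr <- simulate_network(con, sq, duration = 1300, warmup = 100,
                         record_state = TRUE)
  mgn <- con$units[!con$units$cortical, ]
  ref <- t(vapply(tr$times, function(t) afferent_input(sq, t),
                  numeric(16)))
  got <- tr$input[, mgn$unit[order(mgn$channel)]]
  expect_equal(got, ref, ignore_attr = TRUE, tolerance = 1e-12)
})
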