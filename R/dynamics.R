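#' Dynamics parameters
#'
#' Time constants and options for the column state equations.  Membrane
#' potentials `u` (excitatory) and `v` (inhibitory) decay with `tau_m` and
#' are transformed into mean firing rates by [firing_rate()].  Synaptic
#' efficacies `q` (one per column; all connections leaving a column share
#' its efficacy) deplete with the presynaptic rate on the onset time
#' constant `tau_o` (slower in cortex than in the MGN) and recover on
#' `tau_rec`, which is the experiment-specific free parameter of the model.
#'
#' @param tau_m membrane time constant, ms.
#' @param theta firing threshold.
#' @param tau_o_cortex,tau_o_thalamus depression onset time constants, ms.
#' @param tau_rec depression recovery time constant, in seconds.
#' @param dt integration step, ms; must satisfy `dt <= tau_m / 10`.
#' @param depress_inhibitory if `TRUE` (default), the within-column
#'   inhibitory drive is scaled by the column's efficacy (`q * g(v)`),
#'   matching the efficacy scaling of both terms of the excitatory state
#'   equation; `FALSE` uses the undepressed `g(v)`.
#' @param depress_ie if `TRUE` (default), the lateral excitatory drive onto
#'   inhibitory populations (`W_ie`) uses the same depressed presynaptic
#'   rate `q * g(u)` as all other connections leaving the column; `FALSE`
#'   uses the undepressed `g(u)`.
#' @param stsd if `FALSE`, synaptic depression is disabled and `q` is pinned
#'   at its initial value (see [knockout_stsd()]).
#' @return A list of class `dynamics_params`.
#' @export
dynamics_params <- function(tau_m = 30, theta = 0.05,
                            tau_o_cortex = 100, tau_o_thalamus = 20,
                            tau_rec = 1.2, dt = 1,
                            depress_inhibitory = TRUE, depress_ie = TRUE,
                            stsd = TRUE) {
  if (any(c(tau_m, tau_o_cortex, tau_o_thalamus, tau_rec, dt) <= 0))
    stop("all time constants and dt must be positive")
  if (dt > tau_m / 10)
    stop("dt must be <= tau_m / 10 for a stable explicit-Euler advance")
  structure(list(tau_m = tau_m, theta = theta,
                 tau_o_cortex = tau_o_cortex,
                 tau_o_thalamus = tau_o_thalamus,
                 tau_rec = tau_rec, dt = dt,
                 depress_inhibitory = isTRUE(depress_inhibitory),
                 depress_ie = isTRUE(depress_ie),
                 stsd = isTRUE(stsd)),
            class = "dynamics_params")
}

#' Disable short-term synaptic depression
#'
#' Returns a copy of `params` in which the synaptic efficacies are pinned at
#' 1 for all units and times; all other dynamics are unchanged.  Used for
#' knockout comparisons: without depression the network produces no
#' mismatch response.
#'
#' @param params a `dynamics_params`.
#' @return A `dynamics_params` with depression disabled.
#' @export
knockout_stsd <- function(params) {
  stopifnot(inherits(params, "dynamics_params"))
  params$stsd <- FALSE
  params
}

#' Mean firing rate of a lumped population
#'
#' `g(x) = H(x - theta) * tanh(2 (x - theta) / 3)`: zero at and below the
#' firing threshold, saturating towards 1 above it.  (At `x == theta` the
#' Heaviside convention is immaterial since `tanh(0) = 0`.)
#'
#' @param x membrane potential(s).
#' @param theta firing threshold.
#' @return Firing rate(s) in `[0, 1)`.
#' @examples
#' firing_rate(1.55)   # tanh(1) ~ 0.7616
#' @export
firing_rate <- function(x, theta = 0.05) {
  ifelse(x > theta, tanh(2 * (x - theta) / 3), 0)
}

# per-unit depression onset time constants (ms)
.tau_o_vector <- function(connectome, params) {
  ifelse(connectome$units$cortical, params$tau_o_cortex,
         params$tau_o_thalamus)
}

#' Time derivatives of the column state equations
#'
#' Reference (pure R) implementation of the drift:
#' \deqn{\tau_m \dot u = -u + W_{ee} r - W_{ei} g_{inh} + i_{aff}}
#' \deqn{\tau_m \dot v = -v + W_{ie} r}
#' \deqn{\dot q = -q \circ g(u) / \tau_o + (1 - q) / \tau_{rec}}
#' where \eqn{r = q \circ g(u)} is the depressed presynaptic rate shared by
#' all connections leaving a column (undepressed in the `W_ie` term when
#' `depress_ie = FALSE`) and \eqn{g_{inh} = g(v)} (optionally depressed).
#' The compiled
#' integrator advances exactly this drift; this function exists for
#' inspection, testing and use with external ODE solvers.
#'
#' @param state list with numeric vectors `u`, `v`, `q` of equal length.
#' @param input afferent input vector (same length; nonzero only on MGN
#'   units in the full model).
#' @param connectome a `connectome`.
#' @param params a `dynamics_params`.
#' @return list with vectors `du`, `dv`, `dq`.
#' @export
drift <- function(state, input, connectome, params = dynamics_params()) {
  n <- nrow(connectome$units)
  if (length(state$u) != n || length(state$v) != n || length(state$q) != n ||
      length(input) != n)
    stop("state/input length does not match the connectome (", n, " units)")
  gu <- firing_rate(state$u, params$theta)
  gv <- firing_rate(state$v, params$theta)
  r <- if (params$stsd) state$q * gu else gu
  r_ie <- if (params$depress_ie) r else gu
  ginh <- if (params$depress_inhibitory && params$stsd) state$q * gv else gv
  du <- (-state$u + as.numeric(connectome$W_ee %*% r) -
           connectome$w_ei * ginh + input) / params$tau_m
  dv <- (-state$v + as.numeric(connectome$W_ie %*% r_ie)) / params$tau_m
  dq <- if (params$stsd) {
    -state$q * gu / .tau_o_vector(connectome, params) +
      (1 - state$q) / (params$tau_rec * 1000)
  } else {
    rep(0, n)
  }
  list(du = du, dv = dv, dq = dq)
}

#' Integrate the network dynamics over a stimulus sequence
#'
#' Advances the state equations with a fixed-step explicit Euler scheme from
#' rest (`u = v = 0`, `q = 1`) through a silent warm-up followed by the
#' stimulus protocol, recording the MEG proxy signal at every step.  The run
#' is fully deterministic given the sequence.  Trajectories of all state
#' variables can be recorded for small runs with `record_state = TRUE`.
#'
#' @param connectome a `connectome`.
#' @param sequence a `stimulus_sequence` (or its event data.frame), or
#'   `NULL` for a silent run.  Tone events are delivered to the MGN unit of
#'   their tonotopic channel with linear on/off ramps of `ramp` ms.
#' @param params a `dynamics_params`.
#' @param meg a `meg_params` controlling the MEG read-out weights.
#' @param duration recorded duration in ms; defaults to the sequence's
#'   total duration plus 600 ms tail.
#' @param warmup silent warm-up before the first recorded sample, ms.
#' @param record_state record full `u`, `v`, `q` and input trajectories
#'   (memory-guarded; intended for short diagnostic runs).
#' @param init optional initial state list (`u`, `v`, `q`); default rest.
#' @param ramp tone envelope ramp duration, ms.
#' @return An object of class `trajectory`: `times` (ms, 0 at the start of
#'   the protocol), `dt`, `meg` (the class-weighted MEG proxy), `q_range`,
#'   `g_max`, `final_state`, and -- when recorded -- matrices `u`, `v`, `q`,
#'   `input` of size T x N.
#' @export
simulate_network <- function(connectome, sequence = NULL,
                             params = dynamics_params(),
                             meg = meg_params(),
                             duration = NULL, warmup = 2000,
                             record_state = FALSE, init = NULL, ramp = 5) {
  stopifnot(inherits(connectome, "connectome"))
  stopifnot(inherits(params, "dynamics_params"))
  units <- connectome$units
  n <- nrow(units)
  events <- NULL
  if (!is.null(sequence)) {
    events <- if (inherits(sequence, "stimulus_sequence")) sequence$events
              else sequence
    if (is.null(duration))
      duration <- (if (inherits(sequence, "stimulus_sequence"))
                     sequence$total_duration
                   else max(events$onset + events$duration)) + 600
  }
  if (is.null(duration)) stop("duration required for a silent run")
  dt <- params$dt
  n_steps <- as.integer(round((warmup + duration) / dt))
  record_from <- as.integer(round(warmup / dt))
  n_rec <- n_steps - record_from
  if (record_state && as.double(n_rec) * n > 2e7)
    stop("record_state = TRUE would store ", n_rec, " x ", n,
         " samples; use a shorter run")

  if (is.null(events) || nrow(events) == 0) {
    ev_onset <- ev_dur <- ev_amp <- numeric(0)
    ev_unit <- integer(0)
  } else {
    mgn <- units[!units$cortical, ]
    if (nrow(mgn) == 0) stop("connectome has no thalamic units")
    keep <- events$amplitude > 0
    ev <- events[keep, , drop = FALSE]
    ev <- ev[order(ev$onset), , drop = FALSE]
    if (any(ev$channel < 1 | ev$channel > nrow(mgn)))
      stop("event channel outside the MGN tonotopic range 1..", nrow(mgn))
    ev_onset <- ev$onset + warmup
    ev_dur <- ev$duration
    ev_amp <- ev$amplitude
    ev_unit <- mgn$unit[match(ev$channel, mgn$channel)] - 1L
  }

  if (is.null(init)) init <- list(u = rep(0, n), v = rep(0, n), q = rep(1, n))
  ee <- connectome$entries
  ie <- Matrix::summary(connectome$W_ie)
  megw <- meg_presyn_weights(connectome, meg)
  res <- simulate_cpp(
    ee_pre = ee$pre - 1L, ee_post = ee$post - 1L, ee_w = ee$weight,
    ie_pre = ie$j - 1L, ie_post = ie$i - 1L, ie_w = ie$x,
    wei = connectome$w_ei, megw = megw,
    tau_o = .tau_o_vector(connectome, params),
    tau_m = params$tau_m, theta = params$theta,
    tau_rec = params$tau_rec * 1000, dt = dt,
    depress_inh = params$depress_inhibitory,
    depress_ie = params$depress_ie, stsd = params$stsd,
    ev_onset = ev_onset, ev_dur = ev_dur, ev_amp = ev_amp,
    ev_unit = ev_unit, ramp = ramp,
    n_steps = n_steps, record_from = record_from,
    record_state = record_state,
    u0 = init$u, v0 = init$v, q0 = init$q)

  structure(list(
    times = seq(0, by = dt, length.out = n_rec),
    dt = dt,
    meg = res$meg,
    q_range = c(res$q_min, res$q_max),
    g_max = res$g_max,
    u = res$u, v = res$v, q = res$q, input = res$input,
    final_state = list(u = res$u_final, v = res$v_final, q = res$q_final),
    units = units, params = params, meg_params = meg
  ), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory:", length(x$times), "samples at dt =", x$dt, "ms;",
      nrow(x$units), "units;",
      if (is.null(x$u)) "MEG proxy only" else "full state recorded", "\n")
  cat(sprintf("  q range [%.4f, %.4f], max firing rate %.4f\n",
              x$q_range[1], x$q_range[2], x$g_max))
  invisible(x)
}
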