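# Shared fixtures, built once per test run.

default_con <- local({
  con <- NULL
  function() {
    if (is.null(con)) con <<- build_connectome(default_anatomy())
    con
  }
})

# a two-field toy network (1 thalamic unit -> 1 core unit) with narrow
# kernels so that they fit the single-column fields
toy_anatomy <- function() {
  new_anatomy(
    fields = data.frame(name = c("X", "MGN"), level = c("core", "thalamus"),
                        n_columns = 1L),
    edges = data.frame(from = c("MGN", "X"), to = c("X", "MGN"),
                       class = c("feedforward", "feedback"))
  )
}

toy_connectome <- function(w_self = 0.3, gain_tc = 1, fb_ratio = 0.5,
                           gain_ie = 0.5, w_ei = 0.5) {
  build_connectome(toy_anatomy(), connectivity_params(
    gain_ff = c(thalamocortical = gain_tc, core_belt = 0, belt_parabelt = 0),
    fb_ratio = fb_ratio,
    sigma = c(thalamocortical = 0.1, core_belt = 0.1, belt_parabelt = 0.1),
    w_self = w_self, lat_exc = 0, gain_ie = gain_ie, sigma_ie = 1,
    ie_span = 0L, w_ei = w_ei))
}

# single 50-ms probe tone event table
probe_tone <- function(channel = 7, duration = 50, amplitude = 1,
                       onset = 0) {
  data.frame(onset = onset, duration = duration, channel = channel,
             amplitude = amplitude, condition = "probe", sequence_id = 1L)
}

# 99% two-sided binomial bounds on a count
binom_bounds99 <- function(n, p) {
  stats::qbinom(c(0.005, 0.995), n, p)
}
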