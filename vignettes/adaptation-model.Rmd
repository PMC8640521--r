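---
title: "An adaptation-model account of mismatch responses: model, calibration and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An adaptation-model account of mismatch responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptmmn)
```

## The model

`adaptmmn` simulates a hierarchical network of lumped cortical columns.
Each column contains an excitatory and an inhibitory mean-field population
with membrane potentials $u$ and $v$, a firing-rate function
$g(x) = H(x-\theta)\tanh\!\big(\tfrac{2}{3}(x-\theta)\big)$ with threshold
$\theta = 0.05$, and a single synaptic efficacy $q \in (0,1]$ governing all
connections that leave the column:

$$\tau_m \dot u = -u + W_{ee}\,(q \circ g(u)) - W_{ei}\, g(v) + i_\mathrm{aff}(t)$$
$$\tau_m \dot v = -v + W_{ie}\,(q \circ g(u))$$
$$\dot q = -\,q \circ g(u)/\tau_o + (1-q)/\tau_\mathrm{rec}$$

with $\tau_m = 30$ ms, depression onset $\tau_o = 100$ ms in cortex and
20 ms in the thalamic field, and recovery $\tau_\mathrm{rec}$ of order
seconds. Depression is the model's only memory beyond the membrane time
constant: at any moment the pattern of the 224 efficacies is a decaying
imprint of the last few seconds of stimulation, and every "mismatch"
phenomenon the package reproduces is read out of that imprint by the
network's recurrent dynamics.

Two readings of the state equations are genuinely open and are both
implemented:

* **Which presynaptic rate drives lateral inhibition.** Because every
  connection leaving a column shares the column's efficacy, the default
  applies the depressed rate $q\,g(u)$ to the excitatory-to-inhibitory
  drive $W_{ie}$ as well (`depress_ie = TRUE`). The alternative, an
  undepressed $g(u)$ in that term only, is available as
  `depress_ie = FALSE`.
* **Whether the within-column inhibitory synapse depresses.** The default
  (`depress_inhibitory = TRUE`) scales the within-column inhibitory term
  by the column's $q$, so depression weakens both terms of the excitatory
  state equation symmetrically; `depress_inhibitory = FALSE` uses the
  undepressed $g(v)$, on the reading that the efficacy dynamics are
  driven by excitatory firing and the inhibitory population is a
  different cell population.

Neither switch changes any structural property of the model, but they
matter quantitatively: with depression confined to the excitatory
pathway, every repetition suppresses, whereas the symmetric default also
*releases* inhibition on repeated stimulation, which is what lets an
unexpected repetition evoke a larger response than an alternating
standard (the repetition MMN).

## Anatomy and connectivity

The default network (`default_anatomy()`) has 13 cortical fields of 16
tonotopic columns (208 cortical columns) in three tiers — core R, RT, AI;
belt AL, RTL, RTM, RM, MM, CM, CL, ML; parabelt RPB, CPB — plus the 16-unit
MGN, for 224 units. The belt field that some parcellations label "RN" is
named RM here; configuration files may use either. The MGN projects to the
three core fields; each core field projects to its neighbouring belt
fields; anterior belt converges on RPB and posterior belt on CPB; every
feedforward projection is reciprocated feedback, plus one feedback-only
projection CPB→RM. The adjacency is data (editable YAML), not code,
because the anatomical literature underdetermines the oblique connections.

`build_connectome()` realises the anatomy with three weight families:

* between-field topographic kernels — Gaussians over channel offset,
  truncated at $3\sigma$ and normalised to the pathway gain — a narrow
  thalamocortical kernel ($\sigma$ = 0.5 channel units) followed by broad
  cortico-cortical kernels (2.45 core–belt, 2.20 belt–parabelt), whose
  successive convolution widens the afferent receptive fields from MGN
  towards the parabelt (at the shipped gains the higher tiers operate
  near saturation during stimulation, so this breadth shows in the
  pattern of synaptic depression rather than in momentary rate
  profiles); kernels wider than a field are rejected rather than
  wrapped;
* intra-field excitation — within-column self-feedback plus ±1 lateral
  excitation;
* inhibition — each column's excitatory population drives the inhibitory
  populations of columns within `ie_span` channels ($W_{ie}$), and each
  inhibitory population projects back strictly onto its own column's
  excitatory population ($W_{ei}$, diagonal). All weights are nonnegative;
  inhibition enters through the sign of the state-equation term.

## What the weight magnitudes mean and how they were chosen

The anatomy, time constants, thresholds, stimulus parameters and the MEG
class weights (−2, +1, +1) are fixed by the modelling literature the
package follows. The weight *magnitudes* are not published anywhere and
are free parameters of this implementation. Two calibration instruments
exist:

1. a single-tone probe (`calibrate_gains()`): scale the pathway gains so
   that a 50-ms tone from rest drives peak core firing into a
   mid-dynamic-range band (0.3–0.8) and cortical activity falls below 1%
   of its peak within 600 ms of tone offset;
2. a battery stage: among candidate gain sets, select for the qualitative
   orderings of the five-experiment battery, confirmed at more than one
   protocol seed.

The shipped defaults come from the second stage, and deliberately *not*
from the first, because the two stages turned out to be incompatible in
this model family. The probe constraints select transient networks whose
activity dies promptly after each tone; in every such network we found,
an unexpectedly repeated tone evokes a *smaller* response than the
alternating standard (ratio ≈ 0.6) — classic repetition suppression, the
straw-man behaviour. The repetition MMN instead requires a
feedback-dominated regime in which recurrent activity decays slowly
enough that, at a 500-ms onset interval, the next tone arrives on a
residual of the previous response; depression then modulates whether that
residual amplifies or suppresses the incoming tone. The shipped defaults
sit in this reverberant regime: a lone tone from rest drives core firing
into saturation and its tail outlasts the probe's 600-ms settling
horizon, but under ongoing stimulation — the regime every experiment
actually probes — depression keeps the state bounded and the battery
orderings emerge with margin. `calibrate_gains()` retains the probe
constraints as defaults and reports infeasibility honestly when a gain
family cannot satisfy them.

Two failure modes bracket the shipped values: with even more recurrent
excitation the network answers every deviant with an unrealistically
large, late discharge, while with strong inhibition-stabilisation the
response *increases* when efficacies drop, inverting the classic oddball
ordering (the adapted standard out-responds the deviant). The repetition
MMN and the frequency MMN pull in opposite directions along this axis,
which is precisely why the naive "adapted channels respond less" picture
is too small a summary of the model.

## Stimulus protocols

All five generators produce seeded event tables (`onset`, `duration`,
`channel`, `amplitude`, `condition`, `sequence_id`) with TSV round-trip
support. Onset intervals are onset-to-onset throughout. Tones are
rectangular with 5-ms linear ramps; amplitude (default 1) and envelope are
conventions of this implementation, as the source literature does not
specify them. Omissions are zero-amplitude events that keep the expected
onset and channel so epochs can lock to them. Deviant placement is
unconstrained Bernoulli by default (`min_separation` optionally forbids
immediate repeats of the deviant); the "unexpected repetition" of the
alternating paradigm replaces the scheduled high tone, keeping the grid
isochronous. Default sizes give at least 400 epochs of every condition of
interest (e.g. 5000 slots at 10% omissions); `smoke = TRUE` scales down to
tens of epochs for quick runs that do not match the full averaging depth.

## Numerics

The state equations are advanced by fixed-step explicit Euler at
`dt` = 1 ms (guarded by `dt ≤ tau_m/10`, i.e. 33 steps per membrane time
constant). The choice is validated two ways in the test suite: a toy
network integrated at fine `dt` against an independent adaptive-step
solver (deSolve's lsoda) to < 0.1% relative error, and a step-halving
check on the full network's single-tone response (< 5% peak change). `q`
is clipped to $[0,1]$ after each step as a numerical guard; the continuous
dynamics cannot leave that interval from $q(0)=1$. A zero-input network
started from rest stays exactly at rest under Euler, which the tests
assert bit-exactly. The integrator aborts with the offending unit and time
if the state ever becomes non-finite. At exactly $x=\theta$ the Heaviside
convention is immaterial because $\tanh(0)=0$.

The compiled core skips silent presynaptic columns (their rate is exactly
zero below threshold), which makes quiet stretches cheap. The default
battery simulates 5000 omission slots, 20 000 alternating tones, 2 × 3000
five-tone sequences, 2 × 5000 oddball/control tones and 2500
anisochronous tones — about seven hours of stimulation, or 27 million
integration steps — and completes, with ERF processing, in a few minutes
on one CPU.

## ERF processing

The MEG proxy is computed at every step as the class-weighted sum of
excitatory input currents to cortical excitatory populations; because all
connections from column $j$ carry the same current $q_j\,g(u_j)$, the sum
collapses to a fixed per-column weight vector (`meg_presyn_weights()`),
and the same formula with $q \equiv 1$ reproduces the knockout read-out
exactly. Epochs of (−100, +400) ms — (−100, +600) ms for the local–global
experiment, whose effect is late — are averaged per condition, the mean
over (−100, 0) ms subtracted, and the average filtered with a zero-phase
second-order Butterworth highpass at 1 Hz with odd-reflection padding.
Filtering the *average* (not single trials) follows the processing order
of the source description; zero phase avoids shifting peak latencies. Peak
metrics take the extremum of the absolute waveform in a (50, 350) ms
search window — (50, 500) ms for the local–global experiment — both
conventions of this package, since no search windows are published.

## What the experiments test, and what they do not

The five experiments are driven entirely by synthetic protocols; the
package contains no empirical recordings. A passing battery therefore
shows that *this network with these calibrated gains* reproduces the
qualitative mismatch phenomenology — omission responses at fast rates
(with the late omission-peak latency that the modelling literature itself
reports), repetition MMN, a late global-deviance differential, oddball
deviance exceeding the equiprobable control, and deviance under jittered
timing, all abolished when `q` is pinned at 1 — not that cortical tissue
realises these mechanisms, and not that the simulated waveform shapes
match recorded ERFs (no numeric waveforms exist to compare against).
Protocol statistics are checked against their nominal rates with 99%
binomial bounds, so the stimulus side of each claim is independently
verified.

One battery item is reported as not reproduced, deliberately. In the
local–global experiment the *difference wave* between the five-tone
repetition sequence heard as a global deviant versus as a global standard
is reproducibly nonzero and peaks tens of milliseconds later than the
frequency MMN — the late, higher-order signature. But the *peak
amplitudes* of the two condition waveforms sit at parity (ratio
0.99–1.00 across seeds and across several hundred candidate gain sets).
The parity appears structural under this package's connectivity rules:
the two block contexts differ only in (i) the repeated channel's
cumulative load, which the four within-sequence repetitions at 150-ms
spacing drive to the same adaptation floor in both blocks by the fifth
tone, and (ii) the other channel's load, which can reach the repeated
channel's representation only through the parabelt overlap region — and
that region receives nearly identical total drive in both blocks. The
corresponding test is therefore expected to fail at the shipped
defaults, and the limitation is stated here openly.

The generator emulates the event structure of real MMN experiments
(probabilities, intervals, at least 400 presentations per condition) but
none of the measurement side of real data: no sensor noise, no trial
rejection, no subject variability. Effect *orderings* transfer to that
setting; effect sizes do not.

## Known limitations

* No axonal delays, laminar structure, or cell-type diversity beyond the
  lumped e/i pair; no Hebbian or other long-term plasticity; no input from
  outside auditory thalamocortex (e.g. inferior frontal cortex).
* The MEG proxy is a current sum, not a forward model; amplitudes are in
  arbitrary units and only ratios and latencies are meaningful.
* Weight magnitudes are calibrated, not measured; gain sets satisfying
  the single-tone probe constraints fail the repetition-MMN ordering and
  vice versa (see the calibration section), and the local–global
  peak-amplitude ordering is not reproduced at all under these
  connectivity rules. The structural results (counts, bounds, oracle
  agreement, protocol statistics) are insensitive to the gains.
* In the shipped reverberant regime a lone tone from rest saturates the
  core fields; firing rates remain strictly below 1 and all state
  variables bounded, but single-probe responses should not be
  interpreted quantitatively.
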