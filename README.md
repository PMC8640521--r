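# adaptmmn

Neural mass simulations of auditory cortex in which short-term synaptic
depression (STSD) — not a dedicated change detector — generates the
mismatch negativity (MMN).

## The scientific problem

In oddball stimulation, rare *deviant* sounds evoke much larger
event-related responses than frequent *standards*; the difference wave is
the MMN. Two broad explanations compete. Predictive-coding accounts
postulate explicit prediction and error signals. The *adaptation* account
holds that the same mechanism that represses responses to repeated sounds —
activity-dependent synaptic depression inside an interconnected,
tonotopically organised cortical hierarchy — also produces the MMN, with no
separate MMN generator. The classic objections to adaptation (omission
responses, repetition MMN, the multi-standard control) target a straw-man
version in which isolated frequency channels adapt independently. This
package implements the network version and reproduces those "impossible"
MMNs.

## The model

The dynamical unit is a lumped cortical column with an excitatory and an
inhibitory population, described by membrane potentials `u` and `v`:

    tau_m u' = -u + W_ee (q ∘ g(u)) - W_ei g(v) + i_aff(t)
    tau_m v' = -v + W_ie (q ∘ g(u))
         q'  = -q ∘ g(u) / tau_o + (1 - q) / tau_rec

with firing rate `g(x) = H(x - θ) tanh(2 (x - θ) / 3)`, threshold θ = 0.05
and membrane time constant `tau_m` = 30 ms. Each column carries one synaptic
efficacy `q ∈ (0, 1]` shared by all of its outgoing connections: depression
onsets quickly (`tau_o` = 100 ms in cortex, 20 ms in thalamus) and recovers
over seconds (`tau_rec`, the per-experiment free parameter).

224 such units form 13 cortical fields of 16 tonotopic columns — three core
(R, RT, AI), eight belt (AL, RTL, RTM, RM, MM, CM, CL, ML), two parabelt
(RPB, CPB) — plus a 16-unit thalamic field (MGN). Afferent input arrives on
16 abstract frequency channels in the MGN; topographic Gaussian projections
connect neighbouring fields feedforward and feedback, with receptive
fields widening from thalamus to parabelt. The MEG proxy
sums the excitatory input currents to cortical excitatory populations,
weighted −2/+1/+1 for feedforward/feedback/intra-field connections.

Five stimulation paradigms are built in: stimulus omission, alternation
with unexpected repetitions, local–global deviance, classic oddball with
the multi-standard (equiprobable) control, and an anisochronous oddball.
ERFs are epoch averages of the MEG proxy, baseline-corrected over the
100 ms before onset and highpass-filtered at 1 Hz.

## Worked example

```r
library(adaptmmn)

con <- build_connectome(default_anatomy())
res <- run_experiment(experiment_config(4, seed = 1, smoke = TRUE))
print(res)
```

```
experiment 4 result
  MMN peak -120.3 at 112 ms
  [ok] deviant_beats_standard
  [ok] oddball_deviant_beats_multistandard_control
```

The MMN peak is the extremum of the deviant-minus-standard difference wave
(in model current units; negative because feedforward currents carry
weight −2): the rare channel-10 tone among channel-9 standards evokes a
response about three times the standard's, and about twice that of the
*same* tone embedded in the equiprobable control sequence — the signature
usually read as refuting adaptation. `smoke = TRUE` runs a shortened
protocol; drop it for the full ≥ 400-epochs-per-condition averages.

```r
erf <- res$erf                      # per-condition waveforms
peak_metric(erf, "control")
#> $amplitude
#> [1] -48.13449
#> $abs_amplitude
#> [1] 48.13449
#> $latency
#> [1] 178
write_erf(erf, "exp4_erf.csv", metrics = res$metrics)
```

A command-line front end is installed with the package
(`inst/exec/adaptmmn`): `make-protocol`, `simulate`, `analyze`, `run` and
`calibrate` subcommands wrap the same functions for shell pipelines.

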