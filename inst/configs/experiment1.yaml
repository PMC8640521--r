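# Experiment 1 defaults; all unspecified sections fall back to the
# package defaults for this experiment (see ?experiment_config).
experiment: 1
seed: 1
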