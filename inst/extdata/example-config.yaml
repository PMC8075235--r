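# Example run configuration for the experiment subcommand / run_experiment().
logic: AND
prevalence: 0.005
n_individuals: 100000
subsample: true
n_replicates: 100
seed: 1
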