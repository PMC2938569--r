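# Example sopdual run configuration. Omitted keys take the package defaults
# (the standard wild-type parameter set and paradigm); unknown keys are
# rejected.
genotypes:
  wildtype:
    pd1: 0.2
  knockout:
    pd1: 0.11
sweep:
  from: 0
  to: 0.70
  by: 0.005
cohort:
  n_per_group: 12
  noise: 0.3
  seed: 1
out_dir: results
seed: 1
log_level: info
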