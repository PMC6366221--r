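# Demo pipeline configuration: a complete synthetic bioassay experiment
# (3 biosensor strains x 4 dose levels x 3 replicates) analysed end to end.
mode: synthetic
seed: 2024
replicates: 3
snr_threshold: 4000
control: RC_0
rc_levels:
  RC_0: 0
  RC_L: 25
  RC_M: 50
  RC_H: 100
weight_strategy: grid
weight_step: 0.1
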