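# Demo configuration for the pkdpanel pipeline.
# Any key omitted here falls back to default_config(); unknown keys are
# rejected by the validator.
seed: 1
output_dir: pkdpanel_demo
locus:
  length: 2000
  n_paralogs: 6
  identity: 0.98
reads:
  depth: 150
  contamination: 0.05
scenarios:
  n_variants: 3
  include_dropout: true
mlpa:
  copy_state:
    ex08: 1
    ex09: 1
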