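# Example swirlkit run configuration (desk-scale swarm training).
# Any key omitted falls back to the documented default; unknown keys are
# rejected by load_config().
seed: 1
env:
  'N': 20    # quote: bare N is a YAML boolean
  T_steps: 150
  d_t: 1.0
  d_cz: 0.15
  F_max: 1.0
  gamma: 0.9
reward:
  r_target: 1.0
  r_pursuit: 0.1
  r_recede: -0.1
  r_intrude: -0.5
training:
  'n': 16    # quote: bare n is a YAML boolean
  lr: 0.001
  updates: 300
  shared: yes
field:
  f0: 0.0
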