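# Example epipair configuration. Any key left out keeps its default.
imaging:
  scale: 2        # pixels per Angstrom
  size: 100       # final image side (100 or 64)
  mode: residue   # residue | atom
  scheme: PIH     # PIH | four_color
  knockout: []    # subset of [P, I, H] to zero out
  d_max: 6        # depth (A) at which opacity reaches its floor
  alpha_min: 0.1
  distance: true  # false disables depth-as-transparency
net:
  channels: 32
  dropout: 0.75
  lr: 0.001
  batch_size: 32
  max_epochs: 200
  early_patience: 10
  plateau_patience: 5
  plateau_factor: 0.1
sampling:
  ratio: 1        # negatives of each kind per positive
  test_frac: 0.2
  n_folds: 10
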