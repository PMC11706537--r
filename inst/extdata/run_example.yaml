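# Example configuration for `isofusion run` (sections mirror pipeline_config()).
test_frac: 0.2
val_frac: 0.1
ae:
  shared_widths: [64, 32]
  bottleneck: 16
  epochs: 200
  gan_weight: 0.1
  patience: 100
gcn:
  hidden: [64, 32, 16]
  epochs: 150
  dropout: 0.5
  a_edges: 10
schedule:
  pretrain_epochs: 150
  joint_epochs: 40
  patience: 20
vcdn:
  lr: 0.001
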