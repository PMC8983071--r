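# Desk-scale 4x configuration: 16x16 -> 64x64, 8-channel networks.
# Small enough to train in minutes on one CPU; used by the shipped
# phantom experiments.
network:
  scale_k: 2
  n_resblocks: 2
  base_channels: 8
training:
  epochs: 41
  batch_size: 4
  lr0: 5.0e-4
  decay_start_epoch: 40
  pool_size: 20
loss_weights:
  lambda1: 1.0
  lambda2: 1.0
  lambda3: 0.7
  lambda4: 0.3
  lambda5: 1.0
  lambda6: 1.0
  lambda7: 1.0
phantom:
  hr_size: 64
  scale: 4
  alveolar_grain: 6
  air_fraction: 0.15
  n_vessels: [6, 10]
  n_bronchi: [2, 4]
seed: 1
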