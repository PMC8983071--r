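# Main 8x configuration: 32x32 clinical patches -> 256x256 micro-CT scale.
# Intended for long training runs on capable hardware.
network:
  scale_k: 3
  n_resblocks: 9
  base_channels: 64
training:
  epochs: 200
  batch_size: 4
  lr0: 1.0e-5
  decay_start_epoch: 100
  pool_size: 50
loss_weights:
  lambda1: 1.0
  lambda2: 1.0
  lambda3: 0.7
  lambda4: 0.3
  lambda5: 1.0
  lambda6: 1.0
  lambda7: 1.0
phantom:
  hr_size: 256
  scale: 8
seed: 1
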