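data:
  n_per_grade: 50
  side_px: 32
  crop_px: ~
  n_confounders:
  - 0
  - 2
  seed: 1
model:
  head: hybrid
  backbone: tiny-test-cnn
  output_dim: 64
  n_qubits: 5
  n_reupload_blocks: 20
  entangler: chain
train:
  epochs: 30
  lr: 0.001
  batch_size: 32
  folds: 5
  split_ratio: 0.8
  lambda_fn: 1.0
  seed: 1
federated:
  clients: 4
  samples_per_client: 250
  rounds: 15
  local_epochs: 1
  seed: 1
eval:
  test_size: 400
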