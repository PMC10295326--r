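# Default desk-scale pipeline configuration.
output_dir: "trabeculagen_run"
seed: 1
phantom:
  n_train: 2
  n_test: 1
  extent_mm: [2.4, 6.4, 6.4]
  voxel_mm: 0.1
  target_bvtv: 0.18
  target_tbth_mm: 0.218
  target_tbsp_mm: 0.934
pairing:
  use_keypoints: true
training:
  iterations: 200
  img_size: 64
  base_width: 4
  d_width: 4
  lambda_r: 0.1
  lambda_f: 1.0
  lr: 1.0e-4
voi:
  diameter_mm: 4
  height_mm: 1.6
evaluation:
  scopes: ["overall", "cancellous"]
  embed_seed: 7
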