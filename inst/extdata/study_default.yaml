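# Default in-silico agreement study: 40 synthetic subjects, IPH contrast
# drawn uniformly on [1.3, 3.0] times the muscle mean, Rician noise, and the
# 150% / 175% / 200% semi-automatic criteria against the level-set proxy.
cohort:
  n_subjects: 40
  ratio_range: [1.3, 3.0]
  inplane_range: [0.8, 1.4]
  axial_range: [1.5, 4.5]
  master_seed: 1
  template:
    grid_shape: [64, 64, 16]
    spacing: [0.31, 0.31, 1.0]
    muscle:
      mean: 100
      sd: 5
    noise:
      model: rician
      sigma: 5
thresholds: [1.5, 1.75, 2.0]
icc_model: twoway-agreement
comparisons:
  - ["150%", "200%"]
  - ["175%", "200%"]
alpha: 0.05
manual_arm: levelset
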