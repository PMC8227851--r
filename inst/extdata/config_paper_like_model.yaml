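# Model-style run: simulate a 523-individual Norwegian-like cohort over the
# 13 typed variants and LOOCV the EC11 panel in the three-category system.
seed: 23
out_dir: runs/model
stages: [simulate, predict, report]
simulate:
  n: 523
  set: model
predict:
  panel: ec11
  system: three_category
report:
  policies: [pmax, 0.5, 0.7]
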