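# Discovery-style run: simulate a 757-individual cohort over all 44 ranking
# variants, rank variables with 100 resampling replicates, then LOOCV the
# EC11 panel in the two-category system.
seed: 17
out_dir: runs/discovery
stages: [simulate, rank, predict, report]
simulate:
  n: 757
  set: discovery
rank:
  panel: discovery44
  reps: 100
  cutoff: 0.003
predict:
  panel: ec11
  system: two_category
report:
  policies: [pmax, 0.7]
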