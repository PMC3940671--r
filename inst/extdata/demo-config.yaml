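# Demo pipeline configuration: simulate a 36-subject cohort, preprocess,
# score with both methods, run the inferential suite and the reliability
# analyses. All stages are deterministic given the seed.
seed: 42
simulate:
  n_subjects: 36
  n_blocks: 3
preprocess:
  rt_min: 200
  rt_max: 1200
  accuracy_threshold: 0.75
score:
  method: both
  normalization: raw
analyze: true
reliability:
  n_perm: 200
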