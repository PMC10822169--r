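# Two-subject smoke configuration: one distance pair, short trials.
seed: 1
subjects: [S1, S2]
distances: [2.0, 3.5]
exercises: [SAL, SAR]
n_reps: 2
analysis:
  common_fps: 30
  max_lag_s: 2
  r2: correlation
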