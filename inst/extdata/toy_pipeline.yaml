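# End-to-end smoke configuration on the toy genome preset
sample_id: toy_sample
genome:
  preset: toy
spacing: 13000
noise_sd: 0.1
baseline_signal: 1000
cna:
  - {chrom: "1", start: 1300000, end: 2600000, shift: 0.58}
  - {chrom: "2", start: 0, end: 1300000, shift: -1.0}
  - {chrom: "X", start: 0, end: 650000, shift: 0.58}
segmentation:
  alpha: 0.01
  n_perm: 200
  min_width: 3
calling:
  gain_thr: 0.2
  loss_thr: -0.2
  min_probes: 3
exclude_chrom: ["X"]
classify:
  bin_mb: 0.5
  n_per_subtype: 8
  noise_sd: 0.3
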