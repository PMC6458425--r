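# Demo study: fully synthetic, seeded, small enough to run in seconds.
seed: 7
out_dir: demo_out
binary_exposure: true
simulate:
  n_individuals: 2000
  n_snps: 40
  true_causal_effect: 0.1
  exposure_h2: 0.05
estimator:
  boot: 200
case_exclusion: false
filter: flat
scan_fractions: [0.1, 0.2, 0.3, 0.4, 0.5]
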