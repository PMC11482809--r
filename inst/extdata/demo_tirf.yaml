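# Demo: simulated TIRF titration analyzed end-to-end (fields are small so
# the demo completes in well under a minute).
seed: 7
out_dir: tirf_demo_out
tirf:
  concentrations: [0.1, 0.2, 0.42, 0.94, 2.0, 4.2, 6.0, 10.0]
  kd: 0.94
  n: 2.7
  field_size: 128
  n_filaments: 10
  radius: 15
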