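# Demo: synthetic curvature/occupancy-coupled volume trajectory measured
# end-to-end (lattice profile, per-strand occupancy, correlations).
seed: 7
out_dir: structure_demo_out
structure:
  n_frames: 5
  max_curvature: 2.0e-4
  n_subunits: 11
  twist: -167
  rise: 27
  window: 10
  zone_radius: 3
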