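# filattice

Helical lattice geometry, decoration occupancy, and cooperative binding
analysis for actin filaments.

## What it is for

Adhesion complexes such as the cadherin-catenin complex, bridged along
F-actin by afadin's coiled-coil, bind filaments cooperatively and
strand-asymmetrically, and that binding is coupled to nanoscale lattice
deformation (curvature, per-strand twist/rise changes). `filattice` is
an R toolkit for the three quantifications this kind of study needs,
for structural biologists and biophysicists working with filament
models, density maps and TIRF binding assays:

* **Geometry** — per-protomer helical twist and rise by screw-axis
  decomposition of inter-subunit rigid transforms (`local_twist_rise`),
  strand decomposition (`strand_profile`), sliding circle-fit curvature
  (`axis_curvature`), filament extension by terminal-subunit
  superposition (`extend_filament`), and labeled Kabsch superposition
  with RMSD reporting (`superpose_rmsd`).
* **Occupancy** — zone segmentation of decorated-filament volumes
  (`split_map`), per-site integrated intensity normalized to the
  strongest site (`site_occupancy`), per-strand/per-frame aggregation
  (`strand_frame_means`), local rigid refinement of site models against
  a map (`fit_site_models`), and rank correlation of occupancy with
  lattice geometry (`occupancy_vs_geometry`).
* **TIRF binding** — rolling-ball background subtraction, Yen
  thresholding, conjunction-mask bound fractions
  (`analyze_tirf_field`), and Hill-equation fitting (`fit_hill`).
* **Synthetic data** — generators for ideal/curved/strand-asymmetric
  filaments, decoration states, Gaussian-rasterized MRC volumes and
  volume libraries, curvature/occupancy-coupled volume trajectories,
  and dual-channel TIRF image pairs with exact ground truth.

The lattice convention is the F-actin 1-start helix: subunit 0 at the
pointed end, strand = index parity, twist right-handed about the
pointed→barbed axis. Canonical F-actin measures twist −167°, rise 27 Å
per subunit; the same-strand (two-subunit) screw is +26°, 54 Å. The
Hill model is `f(c) = A·c^n / (Kd^n + c^n)` with `n > 1` indicating
cooperative binding.

## Worked example

Measure the lattice of an ideal filament, then fit a simulated
cooperative titration end to end:

```r
library(filattice)

## lattice geometry of a 37-subunit ideal filament
model   <- build_ideal_filament(-167, 27, 37)
profile <- local_twist_rise(model, window = 10)
colMeans(profile[profile$central, c("twist", "rise")])
#> twist  rise
#>  -167    27
screw_decompose(step_transform(model, 10, 12))$twist   # same-strand screw
#> [1] 26

## simulated TIRF titration -> mask pipeline -> Hill fit
conc <- c(0.1, 0.2, 0.42, 0.94, 2, 4.2, 6, 10)
fb <- sapply(seq_along(conc), function(i) {
  s <- simulate_tirf(conc[i], kd = 0.94, n = 2.7, seed = 100 + i)
  analyze_tirf_field(s$actin, s$tetramer, radius = 15)$fraction_bound
})
fit_hill(binding_curve(conc, fb))
#> Hill-equation fit: f(c) = A * c^n / (Kd^n + c^n)
#>   Kd        = 0.8946 uM
#>   Hill n    = 2.83  (cooperative)
#>   amplitude = 0.9417
#>   RSS = 0.0001318 over 8 points
```

The measured twist/rise reproduce the generating symmetry exactly, and
the fitted Kd and Hill coefficient recover the simulator's generating
parameters (0.94 µM, 2.7) to within a few percent under realistic
noise. A YAML-configured driver (`run_pipeline`) chains either stage
with deterministic per-stage seeds and a run manifest; demo
configurations ship in `inst/extdata/`.

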