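# hbquat

Quaternary and tertiary transition analysis for hemoglobin-like
tetramers.

## The problem

Human hemoglobin A is an α₂β₂ tetramer whose low-affinity **T** and
high-affinity **R** quaternary conformations differ mainly by a 12–15°
rigid-body rotation of one αβ dimer relative to the other; on top of
that, each subunit has its own internal tertiary **t**/**r**
rearrangement. Analyzing a conformational ensemble of such a tetramer
means answering: *where is each frame between the known quaternary
states, what tertiary state is each subunit in, and how strongly are
the two levels of motion coupled?*

`hbquat` provides the complete toolchain for structural
bioinformaticians and simulators working on this class of problem:

- **Structure I/O** — (multi-model) PDB reading/writing with
  chain→subunit labeling, heme bookkeeping, altloc resolution, and
  common-atom intersection across structures (`read_pdb`,
  `write_multimodel_pdb`, `select_atoms`).
- **Superposition and distances** — weighted Kabsch fits, RMSD, and
  the rotation-sensitive **rotRMSD**: the backbone RMSD of the α2β2
  dimer after superposing only the α1β1 dimer, a distance that
  amplifies the dimer rotation (0.53 nm between the hemoglobin R and T
  crystal structures, versus 0.24 nm for the ordinary fitted RMSD).
- **Reaction coordinates** — a PCA subspace built from reference
  crystal structures (two eigenvectors span the R–R2–T plane), and
  normalized difference-vector projections: +1 at the T/t endpoint, −1
  at R/r, with the raw scale recorded as a half-span in nm
  (`build_xray_pca`, `build_difference_vector`,
  `normalized_projection`).
- **Rigid-body rotation** — α2–β2 center-of-mass axes, axis rotation
  angles, minimal rotation axes, and the full dimer-on-dimer axis/angle
  decomposition (`dimer_axis`, `dimer_rotation_angle`).
- **States and populations** — quaternary state assignment by the
  ±0.5 projection rule and conditional tertiary population histograms
  (`assign_quaternary_state`, `tertiary_population`).
- **Coupling** — histogram mutual information in nats with
  extrapolation to infinite sample size (linear fit in k = 1/n),
  assembled into quaternary↔tertiary MI matrices (`histogram_mi`,
  `extrapolated_mi`, `mi_matrix`).
- **Synthetic ground truth** — a toy-tetramer generator producing
  morphing trajectories with exactly known quaternary progress,
  per-subunit tertiary schedules, tunable coupling and noise
  (`make_toy_tetramer`, `make_transition_trajectory`), so the entire
  pipeline is testable without downloading structures.
- **Pipeline** — `run_analysis()` orchestrates everything from a
  config object or flat key=value file and writes TSV tables with
  provenance headers. Thin command-line wrappers live in
  `inst/scripts/`.

## Worked example

Generate a synthetic T→R transition in which the β subunits are
strongly coupled to the quaternary motion (coupling 0.9) and the α
subunits are nearly independent (0.1), then run the full analysis:

```r
library(hbquat)

toy <- make_toy_tetramer(n_res = 10, quat_angle_deg = 14,
                         tert_amplitude = 0.2, seed = 1)
dir <- file.path(tempdir(), "hbquat-demo"); dir.create(dir)
write_multimodel_pdb(toy$endpoint_T, file.path(dir, "T.pdb"))
write_multimodel_pdb(toy$endpoint_R, file.path(dir, "R.pdb"))
tr <- make_transition_trajectory(toy, morph_spec(
  n_frames = 800,
  couplings = c(alpha1 = 0.1, beta1 = 0.9, alpha2 = 0.1, beta2 = 0.9),
  noise_sigma = 0.01, seed = 2))
write_multimodel_pdb(tr$frames, file.path(dir, "traj.pdb"))

cfg <- analysis_config(
  references = c(T = file.path(dir, "T.pdb"), R = file.path(dir, "R.pdb")),
  trajectory = file.path(dir, "traj.pdb"), seed = 42)
report <- run_analysis(cfg)
report
#> Transition analysis: 800 frames
#>   transition to R: full (min rotRMSD 0.026 nm)
#>   MI(quaternary, subunit) [nats]:
#>     alpha1  0.4303
#>     beta1   1.4387
#>     alpha2  0.4614
#>     beta2   1.3407
```

The report says: the trajectory completed a full transition to the R
endpoint (its rotRMSD to R fell below the 0.3 nm cutoff, reaching
0.026 nm), and the mutual information between the quaternary coordinate
and the tertiary coordinates recovers the built-in asymmetry — the
coupled β subunits share about three times more information with the
quaternary transition (≈ 1.4 nats) than the nearly uncoupled α subunits
(≈ 0.45 nats).

Individual coordinates are available directly:

```r
build_difference_vector(toy$endpoint_T, toy$endpoint_R, "quaternary")
#> quaternary difference vector T(+1) <- R(-1): half span 0.655 nm

toy0 <- make_toy_tetramer(n_res = 10, quat_angle_deg = 14,
                          tert_amplitude = 0, seed = 1)
dimer_rotation_angle(toy0$endpoint_R, toy0$endpoint_T)
#> Rotation: 14.000 deg about (-0.3030, -0.5051, -0.8081)
```

The second call shows the rigid-body decomposition recovering the
generating 14° dimer rotation exactly on a deformation-free toy.

See `vignette("hbquat-methods")` for the underlying models, estimator
design (including why the MI bin count scales as n^(1/3)), and the
construction that makes the synthetic ground truth exact.

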