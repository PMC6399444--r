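# sercatraj

Trajectory analysis of lipid binding-site dynamics in the calcium pump
SERCA.

## The problem

SERCA (the sarco/endoplasmic reticulum Ca²⁺-ATPase) is a ten-helix
transmembrane pump. In its protonated E2 state a single *nonannular* lipid
binds in a cavity between transmembrane helices M2 and M4, and whether that
lipid stabilizes the E2 state is a question usually addressed by comparing
long molecular-dynamics trajectories of the lipid-bound and lipid-free pump.
The comparison rests on a fixed battery of trajectory observables:

- **Contact occupancies.** Per-frame distances *R* between named residue and
  lipid atoms (e.g. the Gln108 side-chain amide vs. the lipid phosphate P),
  summarized as the fraction of frames with *R* ≤ a threshold (closed
  interval, so "*R* ≤ 0.5 nm" means membership in [0, 0.5] nm), and
  hydrogen-bond occupancies under the conventional geometric criterion
  (donor–acceptor ≤ 0.35 nm and donor–H–acceptor angle ≥ 150°).
- **Distance distributions.** Density-normalized histograms of interhelical
  and interdomain distances against crystal-structure reference values.
- **Structural stability.** Kabsch (closed-form SVD) superposition, per-helix
  RMSD profiles (mean ± sd after a common-domain fit), RMSD time series, and
  deterministic leader/medoid clustering of conformations, which resolves
  minority orientations of the lipid headgroup down to a few percent
  population.
- **Essential dynamics.** Cartesian PCA of positional fluctuations after
  alignment: eigendecomposition of the 3N×3N covariance, cumulative-variance
  accounting, and a one-Gaussian least-squares fit to each component's
  projection histogram. Components classify by the coefficient of
  determination *r*² as essential (*r*² < 0.9), partially essential
  (0.9 ≤ *r*² < 0.98) or non-essential Gaussian fluctuations (*r*² ≥ 0.98).
  Two trajectories are compared through the inner-product matrix
  |v⁽ᴬ⁾ᵢ·v⁽ᴮ⁾ⱼ| of their leading eigenvectors.
- **Water wires.** A per-frame wire/no-wire call: breadth-first search for a
  chain of hydrogen-bonded waters connecting a buried proton-release residue
  (Glu309) to a cytosolic acceptor site (Asn101, or Asp800/Glu908 for the
  C-terminal pathway), segmented into events with lifetimes in picoseconds.

Because production MD trajectories are rarely deposited, the package also
ships seeded synthetic-trajectory generators that plant known statistical
structure — two-state distance processes, a prescribed covariance spectrum
with optionally bimodal modes, scheduled three-water wires — so every
analysis stage is verifiable by parameter recovery without running any
simulation.

## Worked example

```r
library(sercatraj)

# A synthetic pore with two scheduled water-wire windows (20 ps/frame)
ws <- make_wire_system(on_windows = rbind(c(10, 15), c(40, 44)),
                       n_frames = 120, frame_interval = 20, seed = 1)
detect_events(ws$trajectory, ws$config)
#> wire_events: 2 event(s) over 120 frames (20 ps/frame)
#>  start_frame end_frame n_frames lifetime_ps   example_path
#>           10        15        6         120 1001,1002,1003
#>           40        44        5         100 1001,1002,1003

# Cartesian PCA on a trajectory with a planted spectrum
px <- make_planted_pca_trajectory(n_atoms = 30,
        eigenvalues = c(4, 2, 1, 0.5, rep(0.1, 8)) * 1e-3,
        n_frames = 20000, seed = 1)
m <- fit_pca(px$trajectory, select_atoms(px$trajectory$topology, "name CA"))
m
#> pc_model: 90 coordinates, trace 0.008328 nm^2; top eigenvalues: 0.00401, 0.00201, 0.00102, 0.000498, 0.000104
components_needed(m, 0.9)
#> [1] 4
classify_gaussianity(project_component(px$trajectory, m, 1))
#> gaussian_fit: A=6.315 mu=-0.0006277 sigma=0.06309 r^2=0.9986 -> non-essential

# Occupancy of a planted two-state contact process
p <- make_distance_process(state_means = c(0.5, 0.8),
                           stationary_weights = c(0.6, 0.4),
                           transition_rate = 1, n_frames = 10000, seed = 1)
occupancy(p$values, c(0, 0.65))
#> occupancy 0.5984 (5984/10000 frames): series in [0, 0.65] nm (closed interval)
```

The wire events recover the planted 6- and 5-frame windows exactly
(120 and 100 ps); the PCA recovers the planted eigenvalues (4, 2, 1,
0.5, …)·10⁻³ nm² and needs 4 components for 90% of the variance by
construction; the first projection is a Gaussian fluctuation (*r*² ≥ 0.98,
non-essential); and the recovered occupancy sits within binomial error of
the planted 0.60 stationary weight.

For a full comparative study (two trajectories, side-by-side tables and an
inner-product matrix), write a YAML configuration and call
`run_analysis("analysis.yaml")`, or use the thin CLI at
`inst/scripts/analyze.R` (`run` / `validate` / `synth`). See the methods
vignette (`vignettes/trajectory-analysis.Rmd`) for the model conventions and
every tunable default.

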