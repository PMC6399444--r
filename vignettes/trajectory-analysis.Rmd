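---
title: "Methods: comparative trajectory analysis of a lipid-binding membrane pump"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative trajectory analysis of a lipid-binding membrane pump}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sercatraj)
```

# Scope and data model

`sercatraj` implements the standard battery of observables used to compare
molecular-dynamics trajectories of the SERCA calcium pump with and without a
nonannular lipid bound between transmembrane helices M2 and M4: contact and
hydrogen-bond occupancies, distance distributions against crystal
references, per-helix RMSD profiles, conformational clustering, Cartesian
PCA with an essential-space classifier and cross-trajectory collinearity,
and hydrogen-bonded water-wire detection. It does not run simulations,
build topologies, assign protonation states, or draw biological
conclusions: it turns trajectories into tables.

Internal units are **nanometres** and **nanoseconds** throughout (event
lifetimes are reported in picoseconds, the natural scale for water wires);
PDB ångströms are converted at the file boundary. Residue numbering follows
the structure file verbatim, so for SERCA1a structures the canonical labels
(Glu309, Asn101, Thr316, …) can be used directly in selection expressions
such as `"resid 309 and name OE1 OE2"`.

Helix and domain definitions are configuration, not code: published SERCA
helix boundary definitions vary between structural studies, so the
package ships a conventional SERCA1a segment map
(`inst/extdata/serca_segments.yaml`, M1–M10 plus the N/P/A headpiece
domains) that users can replace wholesale with `read_segment_map()`. The
M2 range (residues 89–120) and its neighbours are conventions from the
structural literature, not values the analysis derives.

Three trajectory dialects are read and written: PDB structures (parsed via
bio3d), a plain multi-frame XYZ-style text format (atom count line, a
comment line carrying `time_ns=`, one `name x y z` line per atom, in nm),
and a DCD binary dialect (little-endian Fortran unformatted records,
single-precision coordinates in ångströms, CHARMM-style header, no
unit-cell records). Hydrogens are optional in topologies; every
hydrogen-bond criterion declares a distance-only fallback when they are
absent (see below).

# Contacts and occupancies

Distances support three conventions: `min-heavy-atom` (minimum over all
non-hydrogen pairs — the workhorse for residue–lipid contacts),
`named-atom` (two single named atoms, e.g. a side-chain amide nitrogen vs.
the lipid phosphate P), and `center-of-geometry`. The orthorhombic
minimum-image convention applies whenever a frame carries a box.

Occupancy intervals are **closed on both ends**: a threshold quoted as
*R* ≤ 0.5 nm maps to membership in [0, 0.5] nm, so boundary frames count.
Fractions are exact frame counts divided by totals, which makes occupancies
over a disjoint partition of intervals sum to one to machine precision.

The default hydrogen-bond criterion is donor–acceptor heavy-atom distance
≤ 0.35 nm with donor–H–acceptor angle ≥ 150°. These are the conventional
geometric values in trajectory analysis; they are configurable because no
single pair is canonical across force fields. When the topology carries no
hydrogens the criterion degrades to distance-only and the result's
criterion string records the fallback — silent degradation would make
bound-vs-free comparisons quietly incomparable.

The named-atom map for the classic SERCA pairs is likewise configuration:
lipid choline = N, lipid phosphate = P, Gln/Asn side-chain amide N/O,
Thr hydroxyl O, and Cα for the Val223/Lys515/Asp351 interdomain distances.
The histogram default bin width of 0.025 nm resolves the ~0.3 nm peak
separations typical of two-state contact processes (e.g. peaks near 0.5 and
0.8 nm) without fragmenting them.

# Superposition, RMSD and clustering

Superposition uses the closed-form Kabsch solution (SVD of the 3×3
cross-covariance with a determinant correction, so the rotation is always
proper). It is deterministic, exact on rigid-transformed copies, and
degenerate inputs (fewer than three fit atoms, or collinear fit atoms) are
rejected rather than silently fitted. Per-segment RMSD profiles first
superpose each frame on a common fit selection (by default the
all-transmembrane backbone for helix profiles; headpiece backbone for
headpiece traces) and then measure each segment's RMSD over its own atoms;
whether a profile uses backbone or all heavy atoms is a selection-template
argument, with backbone as the shipped default.

Conformational clustering is **leader clustering followed by medoid
re-assignment**: frames are scanned in order and join the first cluster
whose leader lies within the cutoff (default 0.1 nm over the selection's
heavy atoms), otherwise they found a new cluster; representatives are then
recomputed as medoids. The method was chosen for determinism — given a
frame order and cutoff the partition is reproducible bit-for-bit, which a
stochastic k-medoids is not — and because the populations it reports are
what matters for resolving minority headgroup orientations of a few
percent. Permuting the frame order relabels clusters but, on
well-separated states, preserves the partition.

# Essential dynamics

`fit_pca()` optionally superposes every frame on a reference over a fit
selection (for pump work, the 10-helix transmembrane domain), then
eigendecomposes the covariance of the selected atoms' Cartesian
coordinates. Defaults and conventions:

- **Atom set**: Cα of the analysed selection is the customary
  essential-dynamics choice and keeps covariance sizes desk-scale; backbone
  or heavy-atom sets are a selection away.
- **Sign convention**: each eigenvector's largest-magnitude entry is made
  positive, so inner-product comparisons are deterministic (they use
  absolute values anyway).
- **Degeneracy**: adjacent eigenvalues with relative gap < 10⁻⁶ are flagged
  in the model; collinearity between degenerate components is only
  meaningful at the subspace level, and the flag tells the user so.
- **Alignment is optional** (`fit_reference = NULL`): synthetic fixtures are
  generated in a common frame of reference, and aligning them would only
  mix the planted modes with the six rigid-body degrees of freedom. Real
  trajectories should always be aligned.

Projection histograms (50 bins over mean ± 4 sd) are fitted with a single
Gaussian by Levenberg–Marquardt least squares. The fit runs in standardized
units — the coefficient of determination is scale-invariant, and the
untransformed problem is ill-conditioned for the ~0.01–0.1 nm projections
typical of Cα fluctuations. Classification follows the three-band rule on
*r*²: below 0.9 essential, 0.9 to 0.98 partial, at or above 0.98
non-essential. The bands are reproduced exactly at the thresholds
(0.9 itself is partial; 0.98 itself is non-essential), and the classifier
is monotone in *r*² by construction. A non-convergent fit reports its
diagnostics and withholds the classification instead of guessing.

# Water wires

A wire is a purely geometric object: a chain of hydrogen-bonded waters
connecting a source site (e.g. the Glu309 carboxyl oxygens) to a sink site
(the Asn101 carboxamide, or the Asp800/Glu908 carboxylates for the
C-terminal pathway — expressed as a second `wire_config()`, not separate
code). Per frame, a breadth-first search over the water–endpoint H-bond
graph decides wire/no-wire; only path existence matters, matching the
convention that the call is independent of which waters form the chain.
Node expansion is ordered by atom index, so the example path reported for
an event is deterministic.

Defaults: at most 4 bridging waters (observed wires have 3; the bound
caps the search), 0.35 nm distance-only H-bond criterion (water models in
analysis pipelines frequently lack explicit hydrogens at this stage), and a
cylindrical pre-filter of radius 0.8 nm around the source–sink axis, since
the physiological pathway is confined near helices M1/M2/M4 but no crystal
structure defines its geometry — all configurable. Events are maximal runs
of wire-present frames; runs separated by at most `gap_merge_frames` absent
frames merge (default 0, i.e. an event is an uninterrupted run), because no
standard segmentation rule exists and the default is the most conservative
one. Lifetime = inclusive frame count × frame interval, in ps. Raising
the water bound or the distance cutoff can only add present frames, never
remove them.

# Synthetic study conditions

The generators define the conditions under which the package's guarantees
are stated, and their defaults are fixed once:

- `make_distance_process()`: a hidden-state chain whose switch draws the new
  state from the stationary weights, so those weights are exactly the
  stationary distribution. Defaults plant the two-state contact geometry
  with peaks at 0.5 and 0.8 nm and emission sd 0.03 nm. Occupancy-recovery
  experiments use `transition_rate = 1` (states independent between frames)
  because their error budget is the binomial bound ±3·√(p(1−p)/n), which
  presumes uncorrelated frames; histogram-shape experiments use slow
  switching (0.05) to resemble the dwell structure of real contacts.
- `make_planted_pca_trajectory()`: frames are mean + Σₖ aₖ(t)·vₖ with a
  seeded random orthonormal basis. Bimodal components place equal-weight
  wells at ±offset with per-well sigma = offset/3, and the offset is chosen
  so the planted total variance still equals the eigenvalue; at that 3-sigma
  well separation a one-Gaussian fit falls well below the 0.9 *r*² band.
  Recovery experiments use 20,000 frames over 30 atoms (90 coordinates),
  where the top eigenvalues of a (4, 2, 1, 0.5, …)·10⁻³ nm² spectrum come
  back within 5% and the basis overlaps exceed 0.95.
- `make_wire_system()`: chain waters sit at 0.28 nm O–O spacing (safely
  inside the 0.35 nm criterion) during scheduled windows and park on a
  grid with > 0.6 nm mutual spacing (safely outside it) otherwise, so the
  planted wire/no-wire truth is unambiguous. A 6-frame window at 20 ps per
  frame is, by construction, one event of 120 ps.
- `make_multistate_trajectory()`: whole-group translations separated by
  3× the clustering cutoff plus 0.005 nm atomic noise, with populations
  (0.45, 0.30, 0.18, 0.07) — including a sub-8% minority state — as the
  planted clustering truth.

Every generator seeds its own RNG stream and restores the caller's state,
so identical specs give bit-identical fixtures and the pipeline is
deterministic end to end. Planted quantities are returned as sidecar
records; tests recover them rather than re-deriving them from the fixture.

What the fixtures deliberately do not emulate: force-field energetics,
solvent structure, autocorrelated noise beyond the hidden-state chain, and
anharmonicity beyond symmetric two-well modes. Passing the recovery suite
therefore certifies the estimators — not the convergence of any real
simulation, where sampling error, alignment choices and force-field limits
dominate.

A note on reference values: the shipped crystal fragment
(`inst/extdata/e2_m2m4_fragment_synthetic.pdb`) is a synthetic stand-in
built from idealized residue geometry with the Gln108 amide-to-Thr316
hydroxyl separation set at the 0.65 nm E2 crystal arrangement; it exercises
the atom-map and reference-distance machinery, and is labelled synthetic in
its file name and header. For real work, point `frame_distance()` at an
actual crystal structure.

# Problem sizes and numerical choices

The shipped verification suite runs at desk scale: 20,000-frame PCA
recoveries, 50,000-sample classifier replicates (20 seeds), 10,000-frame
occupancy recoveries (20 seeds), 1,000 random scenes for the wire-search
oracle, and a few hundred frames for clustering — sizes at which every
planted effect is resolvable with comfortable statistical margin. Headline
occupancies and event counts from multi-microsecond production trajectories
(e.g. 6 vs. 8 wire events, or 71%/89% crystal-boundary fractions) are
properties of undeposited simulation data, not of this code, and are
deliberately not asserted anywhere; the suite certifies the machinery that
would measure them.

Numerical conventions worth knowing: covariance uses the n−1 denominator
(so a projection's sample variance equals its eigenvalue exactly);
eigenvalues are clamped at zero before reporting; the trace identity
Σλ = total positional variance holds to < 10⁻⁸ relative error;
histograms normalize to Σ density·width = 1 within 10⁻⁹; and degenerate
superposition inputs, zero-variance correlations, empty series and
out-of-range component indices raise typed errors rather than producing
NaNs.
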