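---
title: "Quantifying structural recovery of rehydrated gas-phase proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying structural recovery of rehydrated gas-phase proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Proteins probed in vacuum — by native mass spectrometry, single-particle
imaging, or after lyophilization — compact when their solvent is removed:
collision cross section (CCS), solvent-accessible surface area (SASA) and
molecular volume all shrink, surface side chains collapse onto the body, and
new intramolecular hydrogen bonds replace lost protein–water ones. Putting
such structures back into water ("computational rehydration") largely
reverses the compaction, and comparing rehydrated ensembles against solution
controls and against the vacuum structures tells how much of the native
structure is recovered, and whether perturbations applied in the gas phase
(for instance dipole-orienting electric fields at 0.2 or 0.4 V/nm) leave
permanent marks.

`rehydra` implements the complete analysis battery for that question as a
package over which a small set of numbered scripts (`analysis/01_*.R` …)
drives a reproducible workflow. The molecular-dynamics engine itself is out
of scope: trajectories enter as multi-model PDB replica sets, and a seeded
synthetic generator with closed-form ground truth stands in for MD so every
stage is testable at desk scale.

## Data model

A `topology` carries per-atom names, elements, 0-based residue indices,
solvent flags and van der Waals radii; a `trajectory` is an ordered list of
coordinate `frame`s (Å, times in ps); a `replica_set` groups replicas of one
condition — `solution`, `vacuum@field`, or `rehydration@field`. The study
design is five replicas per condition. All file I/O is multi-model PDB
(via bio3d), with frame times synthesized from a configured stride since PDB
has no time records.

## Backbone measures

**Superposition.** RMSD uses the Kabsch algorithm: SVD of the weighted
cross-covariance, with the smallest singular direction sign-corrected so the
returned rotation is always proper (`det = +1`) — a mirror image never
superposes to zero. Weights are uniform over the selection; mass weighting
differs negligibly for the Cα-only selections used throughout and can be
passed explicitly. Collinear point sets and sets of fewer than three points
are hard errors.

**Three RMSD reference schemes** reproduce the standard rehydration
diagnostics: `first_frame` (how far each replica moved from its own start),
`external_reference` (distance to a shared frame, conventionally the final
structure of a solution control run), and `parent_mapped` (replica *i*
against its own "parent", conventionally the final frame of replica *i* of
the zero-field rehydration). Parent pairing is by replica index; that rule
is an assumption of this package — the convention only requires *some*
per-replica pairing. For the shared external reference we use one solution
structure (replica 1's final frame) rather than per-replica pairing; the
parent-mapped scheme is available if the latter is wanted.

**RMSF** follows the two-step convention: all replicas of a condition are
concatenated, superposed onto the first frame, averaged into an average
structure, then every frame is re-superposed onto that average and the
per-residue root-mean-square deviation about it is reported. One refinement
pass, no iteration to convergence. Per-residue RMSF is the Cα value (the
mean over selected atoms of a residue if a wider selection is given).

A caveat worth knowing: uniform-weight superposition projects out six rigid
degrees of freedom, which redistributes a share `~2/N` of the pooled noise
variance across atoms. With heterogeneous amplitudes this inflates the
apparent fluctuation of quiet residues and deflates loud ones; the effect
shrinks with selection size and compactness. The parameter-recovery tests
therefore use a compact 300-point selection, where planted per-residue
amplitudes `σ_i` are recovered as `σ_i√3` well within 5 % at 2000 frames;
on a short, thin helix the same check can miss by ~8 %. Real proteins sit
in between; RMSF values for very small selections should be read with this
bias in mind.

## Shape measures

**CCS (projection approximation).** The orientation-averaged shadow area of
the union of atomic spheres. Orientations are drawn uniformly over SO(3)
(Shoemake quaternions, seeded); each orientation's shadow is rasterized at
0.2 Å with a uniformly random sub-pixel grid offset. The random offset makes
the per-orientation estimate unbiased — plain pixel-center counting carries
a ~1 % lattice bias at atomic disc sizes — so the mean over orientations
converges to the true projected area with a reported Monte-Carlo standard
error. Default 300 orientations. A points-in-box Monte-Carlo alternative
(`method = "mc"`) cross-checks the rasterizer in the tests. No charge or
temperature dependence: this is the bare projection approximation, and the
known systematic underestimate is addressed by the conventional
multiplicative calibration factor 1.14 (`apply_ccs_calibration()`), applied
only where gas-phase CCS values are compared with experiment.

**SASA (Shrake–Rupley).** Each atom's accessible sphere (`r_i + probe`,
probe default 1.4 Å) is sampled with a deterministic golden-section spiral
(default 960 points, ≥ 16 enforced); a point is exposed when outside every
other accessible sphere. Deterministic given the point count; exact for an
isolated atom; matches the spherical-cap closed form for fused pairs to
better than 1 % at the default density.

**Envelope volume.** Voxel counting of the union of van der Waals spheres
(no probe), default 0.3 Å voxels, refusing voxels larger than the smallest
radius. The estimator is deterministic and converges as the voxel shrinks;
the tests verify the sphere, the disjoint pair, the analytic lens volume of
an overlapping pair, and error reduction under voxel refinement. "Volume"
for a protein is method-dependent; the envelope volume reproduces the
`s³` size-scaling that matters for the compaction analysis.

**Convexity diagnostic.** Cauchy's surface formula says the mean projected
area of a convex body is one quarter of its surface area, so
`A_s(probe 0) / Ω = 4` exactly for a sphere and `≥ 4` for non-convex bodies
(the shadow of a body is contained in the shadow of its convex hull, whose
surface is no larger). `convexity_ratio()` computes both quantities on the
same radii; the acceptance script reports this ratio for a single sphere,
where the only deviation from 4 is Monte-Carlo error.

**Condition statistics and the report table.** Vacuum structures contribute
their (single) frames directly; solution and rehydration runs contribute all
frames of the analysis window, pooled across replicas, to one mean ± sd per
condition. The window default is the last quarter of frames — the last-50-ns
convention for 200 ns production runs. The table layer computes, per metric,

```
Δ_vs_vacuum   = round( mean_f 100 (R_f − V_f) / V_f )
Δ_vs_solution = round( mean_f 100 (R_f − S) / S )
```

with `f` running over field strengths and rounding half away from zero.
All internal values are kept at full precision; rounding is purely a
presentation concern. This arithmetic reproduces the published delta columns
for the four benchmark proteins shipped in
`inst/extdata/compaction_reference.csv` in 23 of 24 cells; the remaining
cell (CTF, CCS vs vacuum) is not consistent with its own printed condition
means (it recomputes to +10 against a printed +9, presumably rounded from
unrounded means not published) and is excluded from the automated
comparison.

## Contacts and hydrogen bonds

Two residues are in contact in a frame when *any* atom–atom distance
between them — hydrogens included — is ≤ 3.5 Å, boundary inclusive.
Sequence-adjacent residues are not excluded, so near-diagonal bands are
expected in the maps. Occupancy is the mean of the per-frame binary
matrices over all windowed frames pooled across replicas; difference maps
are elementwise subtractions in [−1, 1] (+1: contact only in the first
condition); composite panels pack two comparisons into the strictly lower
and upper triangles with a zero diagonal. Neighbour search uses a cell list
at cutoff resolution with a brute-force path retained for cross-checking;
no periodic-image handling (inputs are whole molecules).

Hydrogen bonds use the conventional geometric criterion: donor–acceptor
distance ≤ 3.5 Å and hydrogen–donor–acceptor angle ≤ 30°, donors being N/O
with a hydrogen within 1.2 Å, acceptors N/O, one side protein and the other
solvent (both directions counted, a pair counted once). Both cutoffs are
configurable.

## The synthetic generator

`simulate_replicas()` produces replica sets with the statistical structure
the analysis assumes, and nothing more:

```
X(t) = X_expanded + (s − 1) (X_expanded − centroid) e^{−t/τ} + ε,
ε ~ N(0, σ_residue²) i.i.d. per atom and frame
```

At `t = 0` the conformation is uniformly compacted by `s` about its
centroid; it relaxes exponentially to the expanded reference with time
constant `τ`. Ground truth is closed-form: the noise-free final first-frame
RMSD equals the Kabsch RMSD between compacted and expanded conformations,
planted RMSF is `σ_i√3`, and compact/expanded shape ratios approach `s²`
(areas) and `s³` (volume) — approached from above, since atomic radii do
not shrink with the conformation. The default study conditions mirror the
design being emulated: 5 replicas per condition, compaction scale 0.8,
per-residue jitter 0.25 Å, and a relaxation time a few times shorter than
the run so the window average sits on the expanded plateau. Noise is
independent and isotropic (no covariance between atoms or frames) —
deliberately, so every recovery target has a closed form.

What the generator does *not* emulate: force-field energetics, secondary
structure, correlated collective motions, charge effects, real water
dynamics, or field-orientation torques. Passing tests therefore demonstrate
that the *measurement machinery* is correct and unbiased under known input
statistics — not that any MD-specific behaviour is reproduced.

`make_toy_protein()` builds a helical Cα trace with exact 3.8 Å spacing, an
outward N–H donor and inward carbonyl O per residue, and seeded side-chain
dummies. `add_waters_with_hbonds()` plants `k` waters at ideal bond
geometry (O at 2.9 Å along the N–H direction, water hydrogens pointing
away); a candidate site is accepted only if, under the counting criterion
itself, the new water forms exactly the one intended bond — so the planted
count is exact by construction. `k_far` background waters are placed beyond
8 Å.

## Pipeline and reproducibility

`validate_config()` resolves a YAML (or list) configuration against the
analysis defaults — contact cutoff 3.5 Å, last-fraction-0.25 window, CCS
calibration 1.14, SASA probe 1.4 Å — and reports every problem at once.
`run_pipeline()` executes input → RMSD (three schemes) → RMSF → shape table
→ contact maps → hydrogen bonds, aborts naming the failing stage, and
writes tidy CSVs, dense text matrices and a metadata record containing the
configuration hash. Every random element (generator, CCS orientations,
water placement) is seeded from the configuration, so a rerun reproduces
byte-identical numeric tables; the tests assert this.

Problem sizes in the shipped scripts and tests are chosen for a desk-scale
demonstration: 16–20 residues, 5 replicas × 24 frames, 48 CCS orientations
per frame, 240 SASA points, 0.4 Å voxels. These settings resolve the
compaction/decompaction signal an order of magnitude larger than its noise;
production analyses of real trajectories would raise the CCS orientation
count (≥ 300), SASA density (960) and voxel resolution (0.3 Å), which only
costs time.

## Known limitations

- The projection approximation ignores scattering physics; only the
  multiplicative 1.14 calibration is provided (no power-law calibration).
- Envelope volume is a van der Waals union volume, not a solvent-excluded
  or Voronoi volume; absolute values are method-specific even though ratios
  and trends are robust.
- RMSF from uniform-weight superposition carries the small-selection
  leakage bias discussed above.
- No periodic-boundary handling and no secondary-structure annotation of
  contact-map features.
- The synthetic generator's independence assumptions make recovery targets
  exact but understate the frame-to-frame correlation of real MD, so
  pooled standard deviations on real data mix fluctuation and drift.
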