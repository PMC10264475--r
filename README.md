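# rehydra

Trajectory-ensemble analysis of protein compaction in vacuum and its
reversal upon rehydration.

Proteins taken out of water — electrosprayed for native mass spectrometry,
injected for single-particle imaging, or freeze-dried — compact: their
collision cross section (Ω), solvent-accessible surface area (A<sub>s</sub>)
and volume (V) all shrink as surface side chains collapse and protein–water
hydrogen bonds are replaced by intramolecular ones. Simulating such
structures back in solution largely reverses the compaction. `rehydra` is
for structural-biology and biophysics groups who run (or re-analyse) such
rehydration ensembles and need the full comparison battery between solution
controls, vacuum structures and rehydrated replicas:

- **RMSD** of Cα atoms under three reference schemes — each trajectory's own
  first frame (RMSD<sub>f</sub>), a shared solution-control final structure
  (RMSD<sub>s</sub>), and per-replica zero-field "parent" structures
  (RMSD<sub>zf</sub>) — with Kabsch superposition (proper rotations only)
  and five-replica averaging.
- **RMSF** per residue from concatenated replica trajectories about their
  average structure.
- **Shape metrics**: projection-approximation CCS (orientation-averaged
  shadow area of the atomic spheres, with Monte-Carlo standard errors and
  the conventional ×1.14 empirical calibration), Shrake–Rupley SASA, and
  van der Waals envelope volume — pooled over the last-50-ns-style analysis
  window and summarised per condition as mean ± sd with rounded
  percent-change columns:
  Δ<sub>vs vacuum</sub> = round(mean<sub>f</sub> 100·(R<sub>f</sub> − V<sub>f</sub>)/V<sub>f</sub>),
  Δ<sub>vs solution</sub> = round(mean<sub>f</sub> 100·(R<sub>f</sub> − S)/S).
- **Contact maps**: residue–residue occupancy (any atom pair ≤ 3.5 Å,
  boundary inclusive), difference maps in [−1, 1], and composite
  lower/upper-triangle panels.
- **Hydrogen bonds** between protein and solvent (D–A ≤ 3.5 Å,
  H–D–A ≤ 30°).
- A **seeded synthetic replica generator** (compacted start, exponential
  relaxation to an expanded reference, per-residue Gaussian jitter,
  plantable waters) with closed-form ground truth, so the entire pipeline
  is testable without MD trajectories.

For convex bodies Cauchy's surface formula ties the two area metrics
together, Ω = A<sub>s</sub>/4 (probe 0); the package exposes this as a
convexity diagnostic and reproduces it to Monte-Carlo precision on sphere
fixtures.

## Worked example

```r
library(rehydra)

# a 16-residue toy protein; 5 replicas relaxing from a compacted (s = 0.8)
# start back to the expanded reference over 24 ns
toy <- make_toy_protein(16, seed = 2026)
sim <- simulate_replicas(toy$topology, toy$frame, scale = 0.8,
                         tau_relax = 6000, sigma = 0.25, n_frames = 24,
                         dt = 1000, n_replicas = 5, seed = 2026)

series <- rmsd_replica_series(sim$replica_set, rmsd_scheme("first_frame"))
m <- replica_mean_series(series)
m$values[24]                       # 1.66 +/- 0.04 A across replicas
sim$ground_truth$expected_final_rmsd_f   # 1.59 A, noise-free closed form

# compaction signature: shadow area of the compacted start vs the
# expanded reference
r <- toy$topology$atoms$radius
ccs_projection_approximation(sim$replica_set$replicas[[1]]$frames[[1]]$coords,
                             r, n_rotations = 300, seed = 1)$value  # 166 A^2
ccs_projection_approximation(toy$frame$coords, r,
                             n_rotations = 300, seed = 1)$value     # 214 A^2

# the report-table arithmetic on the shipped reference means
tab <- compaction_table(reference_compaction_means())
tab[tab$protein == "ubiquitin", c("metric", "delta_vs_vacuum_pct",
                                  "delta_vs_solution_pct")]
#  metric delta_vs_vacuum_pct delta_vs_solution_pct
#     ccs                   9                     4
#    sasa                  30                     6
#  volume                  24                     2
round_half_away(apply_ccs_calibration(851, 1.14))  # 970 A^2
```

The final first-frame RMSD (1.66 Å) sits just above the noise-free ground
truth (1.59 Å) because per-residue jitter adds to the conformational
distance; the compacted shadow area (166 Å², ratio 0.78 to the expanded
214 Å²) shrinks less than the pure s² = 0.64 scaling because atomic radii
do not shrink with the conformation. The ubiquitin delta columns and the
970 Å² calibrated CCS match the published reference values shipped in
`inst/extdata/compaction_reference.csv`.

## The analysis workflow

Numbered drivers under `analysis/` run the whole study on the synthetic
system and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R    # replica sets as multi-model PDB + ground truth
Rscript analysis/02_alignment.R   # RMSD (3 schemes), RMSF
Rscript analysis/03_shape.R       # CCS/SASA/volume table, published-mean deltas
Rscript analysis/04_contacts.R    # occupancy/difference/composite maps, H-bonds
Rscript analysis/05_report.R      # one-shot pipeline with config hash
```

`vignettes/rehydration-analysis.Rmd` documents the models, parameter
choices, numerical methods and limitations.

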