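# Shared study definition for the numbered analysis scripts. Everything
# is seeded, so each script reconstructs exactly the same replica sets.

library(rehydra)

study_config <- function() {
  list(
    synthetic = list(
      n_residues = 16, n_side_atoms = 2, n_frames = 24, dt_ps = 1000,
      n_replicas = 5, compaction_scale = 0.8, tau_relax_ps = 6000,
      sigma_A = 0.25, seed = 2026, waters_bonded = 5, waters_far = 10
    ),
    ccs = list(n_rotations = 48),
    sasa = list(n_points = 240),
    volume = list(voxel_A = 0.4),
    out_dir = "results/pipeline"
  )
}

# The seven replica sets of the study design (solution control, vacuum
# structures and rehydration runs at 0.0 / 0.2 / 0.4 V/nm).
study_sets <- function(cfg = validate_config(study_config())) {
  build_synthetic_study(cfg)
}

results_dir <- function(...) {
  d <- file.path("results", ...)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}
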