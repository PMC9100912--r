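# Shared settings for the analysis scripts: one synthetic orchard of 92
# trees (the cohort size of the study design this emulates) on a 400 x 400
# pixel scene, 450-950 nm at 4 nm. Each script regenerates the scene from
# this config, so the whole analysis is a pure function of SCENE_SEED.

library(hypercnc)

SCENE_SEED <- 92L

scene_cfg <- scene_config(
  n_rows = 400, n_cols = 400,
  n_trees = 92, crown_radius = 6, shadow_offset = c(5, 5),
  seed = SCENE_SEED
)

RESULTS_DIR <- "results"
SCRATCH_DIR <- "scratch"
dir.create(RESULTS_DIR, showWarnings = FALSE)
dir.create(SCRATCH_DIR, showWarnings = FALSE)
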