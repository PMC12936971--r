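# Shared configuration for the numbered analysis scripts. Every script
# sources this file, so all stages agree on one cohort, one master seed, and
# one workspace; run_pipeline() caches finished stages, so the scripts can be
# run one after another (or re-run) without recomputing what is done.

library(msnbiotypes)

MASTER_SEED <- 20260922L

demo_config <- function() {
  pipeline_config(
    spec = cohort_spec(n_controls = 300L, n_cases = 200L, n_regions = 60L,
                       n_sites = 4L, n_samples_per_region = 200L,
                       k_true = 3L, effect_size = 3),
    master_seed = MASTER_SEED,
    k_grid = 2:4, n_restarts = 5L, n_folds = 10L,
    n_perm = 1000L, n_surrogates = 1000L,
    n_annotations = 19L, n_terms = 25L, n_boot = 500L)
}

WORKSPACE <- file.path("results", "workspace")
dir.create(WORKSPACE, recursive = TRUE, showWarnings = FALSE)

run_stages <- function(stages) {
  cfg <- demo_config()
  cfg$stage_list <- stages
  run_pipeline(cfg, WORKSPACE)
}
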