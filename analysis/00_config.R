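# Shared study configuration for the analysis scripts. Each numbered script
# sources this file, regenerates its inputs deterministically from the seed,
# and writes its outputs (plus the resolved configuration) under results/.

suppressPackageStartupMessages(library(tractmvpa))

config <- make_run_config(
  seed = 20260927,
  tract = list(n_voxels = 940),          # right-hemisphere tract size
  permutation = list(n_perm = 500),      # desk-scale; the study used 10,000
  bootstrap = list(n_boot = 200)
)

results_dir <- file.path("results")
dir.create(results_dir, showWarnings = FALSE, recursive = TRUE)
write_run_config(config, file.path(results_dir, "run_config.yaml"))

# the two hemisphere skeletons, sized after the study's tract voxel counts
make_study_skeletons <- function(cfg = config) {
  list(right = make_skeleton(cfg$tract$n_voxels, seed = cfg$seed,
                             hemisphere = "right"),
       left = make_skeleton(832, seed = cfg$seed + 1, hemisphere = "left"))
}

make_study_cohort <- function(skeleton, cfg = config, offset = 0) {
  simulate_dti_cohort(skeleton,
                      n_pos = cfg$cohort$n_pos, n_neg = cfg$cohort$n_neg,
                      effect = list(metric = "MD",
                                    amplitude = cfg$cohort$amplitude),
                      noise = list(sd_subject = cfg$cohort$sd_subject,
                                   sd_voxel = cfg$cohort$sd_voxel,
                                   decay = cfg$cohort$decay),
                      seed = cfg$seed + 100 + offset)
}
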