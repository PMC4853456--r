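#!/usr/bin/env Rscript
# Stage 1 -- generate the synthetic study: two tract skeletons (sized after
# the study's left/right uncinate voxel counts), per-subject DTI metric maps
# with the end-localized MD group effect, and the behavioural table.
# Outputs: NIfTI masks and example metric maps, the subject CSV, voxel TSVs.

source(file.path("analysis", "00_config.R"))
out <- file.path(results_dir, "cohort")
dir.create(out, showWarnings = FALSE)

sks <- make_study_skeletons()
for (h in names(sks)) {
  sk <- sks[[h]]
  cat(sprintf("%s skeleton: %d voxels, %d edges, %d connected component(s)\n",
              h, sk$n_voxels, nrow(sk$edges), skeleton_components(sk)))
  write_skeleton_mask(sk, file.path(out, paste0("skeleton_", h, ".nii.gz")))
  write_voxel_table(sk, file.path(out, paste0("voxels_", h, ".tsv")))
}

cohort <- make_study_cohort(sks$right)
cat(sprintf("cohort: %d athletes vs %d controls, implanted MD amplitude %.1e mm^2/s\n",
            sum(cohort$subjects$group == 1), sum(cohort$subjects$group == -1),
            cohort$effect_spec$amplitude))
write_subject_table(cohort, file.path(out, "subjects.csv"))

# one example per-metric map (subject 1) plus the implanted effect field
for (m in names(cohort$features))
  write_voxel_map(cohort$features[[m]][1, ], sks$right,
                  file.path(out, paste0("sub-S001_", m, "_right.nii.gz")))
write_voxel_map(effect_field(sks$right), sks$right,
                file.path(out, "effect_field_right.nii.gz"))

cat("wrote cohort artifacts to", out, "\n")
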