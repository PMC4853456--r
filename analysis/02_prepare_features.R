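#!/usr/bin/env Rscript
# Stage 2 -- tract-map post-processing on a simulated probabilistic
# tractography map: way-total normalization, thresholding at 20% of the
# within-tract 95th percentile (the uncinate convention; 40% for the SLF
# control tract), intersection with the skeleton, and feature assembly.

source(file.path("analysis", "00_config.R"))
out <- file.path(results_dir, "features")
dir.create(out, showWarnings = FALSE)

sk <- make_study_skeletons()$right
cohort <- make_study_cohort(sk)

# emulate a streamline visitation-count map: dense near the seed mid-tract
set.seed(config$seed + 2)
visit <- exp(-((sk$arc - 0.5) / 0.35)^2) + 0.05 * runif(sk$n_voxels)
counts <- round(visit * 4000)
waytotal <- 5000 * 4  # streamline samples retained by the exclusion masks

prob <- normalize_tract_map(counts, waytotal)
mask_uf <- threshold_tract_map(prob, config$tract$threshold_fraction_uf)
mask_slf <- threshold_tract_map(prob, config$tract$threshold_fraction_slf)
cat(sprintf("threshold %.3f retains %d/%d voxels (UF 20%% rule); %.3f retains %d (SLF 40%% rule)\n",
            attr(mask_uf, "threshold"), sum(mask_uf), sk$n_voxels,
            attr(mask_slf, "threshold"), sum(mask_slf)))

voxels <- intersect_with_skeleton(as.vector(mask_uf), sk)
cat(sprintf("skeleton intersection keeps %d voxels in lexicographic order\n",
            length(voxels)))

for (m in c("FA", "MD", "AD", "RD")) {
  Xm <- assemble_feature_matrix(cohort, voxels, metric = m)
  write.csv(data.frame(id = rownames(Xm), Xm, check.names = FALSE),
            file.path(out, paste0("features_", m, ".csv")), row.names = FALSE)
}
writeLines(as.character(voxels), file.path(out, "retained_voxels.txt"))
cat("wrote feature matrices to", out, "\n")
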