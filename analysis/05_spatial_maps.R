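#!/usr/bin/env Rscript
# Stage 5 -- interpretation maps for the right-tract MD run: the voxel-group
# covariance map (positive frontal / negative temporal when recovered), TFCE
# with max-statistic FWE inference, the bootstrap-averaged ElasticNet
# coefficient map, and the coefficient-covariance diagnostics.

source(file.path("analysis", "00_config.R"))
out <- file.path(results_dir, "maps")
dir.create(out, showWarnings = FALSE)

sk <- make_study_skeletons()$right
cohort <- make_study_cohort(sk, offset = 1)
X <- assemble_feature_matrix(cohort, metric = "MD")
y <- cohort$subjects$group

covmap <- group_covariance_map(X, y)
frontal <- sk$end_labels == "frontal"; temporal <- sk$end_labels == "temporal"
cat(sprintf("covariance map: %0.f%% of frontal-end voxels positive, %0.f%% of temporal-end voxels negative\n",
            100 * mean(covmap[frontal] > 0), 100 * mean(covmap[temporal] < 0)))
write_voxel_map(covmap, sk, file.path(out, "covariance_MD_right.nii.gz"))

fwe <- tfce_permutation_fwe(X, y, sk, E = config$tfce$E, H = config$tfce$H,
                            n_perm = config$permutation$n_perm,
                            seed = config$seed + 50)
cat(sprintf("TFCE: minimum FWE-corrected p = %.4g over %d voxels (%d permutations)\n",
            min(fwe$p_fwe), sk$n_voxels, fwe$n_perm))
write_voxel_map(fwe$tfce, sk, file.path(out, "tfce_MD_right.nii.gz"))
write_voxel_map(fwe$p_fwe, sk, file.path(out, "tfce_fwe_p_MD_right.nii.gz"))

boot <- bootstrap_coefficient_map(
  X, y, classifier_spec("enet_lrc", lambda1 = 0.05, alpha = 0.5),
  n_boot = config$bootstrap$n_boot, seed = config$seed + 51)
write_voxel_map(boot$mean_coef, sk, file.path(out, "boot_coef_MD_right.nii.gz"))

diagn <- coef_covariance_diagnostics(boot$mean_coef, covmap)
cat(sprintf("bootstrap coefficients: %d non-zero voxels, sign agreement %.2f, r = %.2f with the covariance map\n",
            diagn$n_nonzero, diagn$sign_agreement, diagn$r))
jsonlite::write_json(list(n_nonzero = diagn$n_nonzero,
                          sign_agreement = diagn$sign_agreement,
                          r = diagn$r, n_boot = boot$n_boot,
                          n_redrawn = boot$n_redrawn),
                     file.path(out, "coef_covariance_diagnostics.json"),
                     auto_unbox = TRUE, digits = NA)
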