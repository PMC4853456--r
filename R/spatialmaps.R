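# Voxelwise interpretation maps: covariance between each voxel and the group
# variable (the interpretable "activation pattern" counterpart of classifier
# weights for two-group designs), TFCE with max-statistic permutation
# family-wise-error inference, bootstrap-averaged linear-classifier
# coefficient maps, and coefficient-vs-covariance diagnostics.

#' Voxel-group covariance map
#'
#' Per voxel, the sample covariance (n-1 denominator) between the feature
#' values and the -1/+1 group coding. A positive value means the +1 (athlete)
#' mean exceeds the -1 (control) mean at that voxel; flipping all labels
#' negates the map exactly.
#'
#' @param X subjects x voxels feature matrix.
#' @param y +1/-1 labels, both classes present.
#' @return numeric vector of per-voxel covariances (a voxel map aligned to
#'   the feature columns).
#' @export
group_covariance_map <- function(X, y) {
  y <- check_labels(y)
  X <- as.matrix(X)
  yc <- y - mean(y)
  as.vector(crossprod(X, yc)) / (length(y) - 1)
}

#' Threshold-free cluster enhancement
#'
#' Integrates cluster extent and height over all thresholds:
#' \deqn{TFCE(v) = \sum_h extent(v, h)^E \, h^H \, dh}
#' summing over thresholds `h = dh, 2 dh, ...` up to the map maximum, where
#' `extent` is the size of v's connected suprathreshold (value >= h) cluster
#' under the skeleton's 26-connectivity adjacency. Negative values are
#' enhanced on the negated map and re-signed, so the map is treated
#' two-sidedly. Defaults E = 0.5, H = 2, dh = max/100 follow the conventions
#' of FSL randomise.
#'
#' @param map per-voxel scalar field (length = skeleton voxel count).
#' @param skeleton a `tract_skeleton`.
#' @param E,H extent and height exponents (>= 0).
#' @param dh integration step; `NULL` means `max(abs(map))/100`.
#' @return per-voxel enhanced map (signed).
#' @export
tfce <- function(map, skeleton, E = 0.5, H = 2, dh = NULL) {
  stopifnot(inherits(skeleton, "tract_skeleton"))
  if (length(map) != skeleton$n_voxels)
    stop("alignment error: map length must equal skeleton voxel count")
  if (!all(is.finite(map))) stop("map must be finite")
  if (E < 0 || H < 0) stop("E and H must be non-negative")
  mx <- max(abs(map))
  if (mx == 0) return(numeric(length(map)))
  if (is.null(dh)) dh <- mx / 100
  if (dh <= 0) stop("dh must be positive")
  if (dh > mx)
    warning("dh exceeds the map maximum; using a single integration step")
  from <- skeleton$edges[, 1] - 1L
  to <- skeleton$edges[, 2] - 1L
  enhance <- function(v) {
    top <- max(v)
    if (top <= 0) return(numeric(length(v)))
    if (dh > top) {
      # one-sided lobe weaker than the step: single step at its maximum
      thr <- top
    } else {
      thr <- seq(dh, top + dh / 2, by = dh)
      thr <- thr[thr <= top + 1e-12]
    }
    as.vector(tfce_cpp(v, from, to, thr, E, H, dh))
  }
  enhance(pmax(map, 0)) - enhance(pmax(-map, 0))
}

#' TFCE permutation inference with family-wise-error control
#'
#' The observed statistic is the two-sided TFCE of the voxel-group covariance
#' map. The null distribution is the maximum absolute TFCE over voxels under
#' random relabelings; following the convention of FSL randomise the
#' unpermuted labelling is included in the null ensemble, so p-values lie in
#' [1/n_perm, 1]. FWE p-values are monotone non-increasing in |TFCE|.
#'
#' @param X subjects x voxels feature matrix (columns = all skeleton voxels).
#' @param y +1/-1 labels.
#' @param skeleton a `tract_skeleton`.
#' @param E,H,dh TFCE parameters (see [tfce()]).
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed.
#' @return list with `covariance` (map), `tfce` (signed map), `p_fwe`
#'   (per-voxel FWE p-values), `null_max` (null maxima, first entry the
#'   observed labelling), `n_perm`, `seed`.
#' @export
tfce_permutation_fwe <- function(X, y, skeleton, E = 0.5, H = 2, dh = NULL,
                                 n_perm = 500, seed = 1) {
  y <- check_labels(y)
  if (n_perm < 1) stop("n_perm must be at least 1")
  covmap <- group_covariance_map(X, y)
  obs <- tfce(covmap, skeleton, E, H, dh)
  null_max <- numeric(n_perm)
  null_max[1] <- max(abs(obs))
  with_seed(seed, {
    for (b in seq_len(n_perm)[-1]) {
      yb <- sample(y)
      null_max[b] <- max(abs(tfce(group_covariance_map(X, yb), skeleton,
                                  E, H, dh)))
    }
  })
  p_fwe <- vapply(abs(obs), function(t) mean(null_max >= t), numeric(1))
  list(covariance = covmap, tfce = obs, p_fwe = p_fwe, null_max = null_max,
       n_perm = n_perm, seed = seed)
}

#' Bootstrap-averaged coefficient map of a linear classifier
#'
#' Subjects are resampled with replacement from the whole sample;
#' hyper-parameters stay fixed at the supplied values (re-optimizing per
#' resample would change the estimand). Resamples that lose a class are
#' redrawn and counted. The per-voxel mean of the raw-scale coefficients over
#' resamples is returned.
#'
#' @param X subjects x voxels feature matrix.
#' @param y +1/-1 labels.
#' @param spec a `classifier_spec` of a linear family (`enet_lrc` or
#'   `tv_lrc`) with fixed hyper-parameters.
#' @param n_boot number of bootstrap resamples (the study used 10,000;
#'   scale to taste).
#' @param seed integer seed.
#' @param D edge-difference operator for `tv_lrc`.
#' @param resampler optional function `(n, b) -> indices`, a test hook; the
#'   default draws with replacement. Passing `function(n, b) seq_len(n)`
#'   makes `n_boot = 1` equal a single full-data fit.
#' @return list with `mean_coef` (per-voxel mean raw-scale coefficients),
#'   `mean_intercept`, `n_boot`, `n_redrawn`, `seed`.
#' @export
bootstrap_coefficient_map <- function(X, y, spec, n_boot = 200, seed = 1,
                                      D = NULL, resampler = NULL) {
  y <- check_labels(y)
  if (!spec$family %in% c("enet_lrc", "tv_lrc"))
    stop("bootstrap coefficient maps require a linear family")
  if (n_boot < 1) stop("n_boot must be at least 1")
  X <- as.matrix(X)
  n <- nrow(X)
  acc <- numeric(ncol(X)); b0 <- 0; redrawn <- 0L
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- if (is.null(resampler)) sample(n, n, replace = TRUE)
               else resampler(n, b)
        if (length(unique(y[idx])) == 2) break
        redrawn <- redrawn + 1L
      }
      fit <- suppressWarnings(
        train_classifier(X[idx, , drop = FALSE], y[idx], spec, D = D))
      cf <- coef(fit)
      acc <- acc + cf$coefficients
      b0 <- b0 + cf$intercept
    }
  })
  list(mean_coef = acc / n_boot, mean_intercept = b0 / n_boot,
       n_boot = n_boot, n_redrawn = redrawn, seed = seed)
}

#' Sign-agreement and correlation between coefficient and covariance maps
#'
#' Computed over the support of the coefficient map (voxels with non-zero
#' coefficients), where sparse-classifier coefficients are defined.
#'
#' @param coefs per-voxel coefficient map.
#' @param covs per-voxel covariance map of the same length.
#' @return list with `sign_agreement`, `r` (Pearson over the support, `NA`
#'   if fewer than 3 support voxels or degenerate), `n_nonzero`, `support`.
#'   All-zero coefficient maps give an explicit empty result.
#' @export
coef_covariance_diagnostics <- function(coefs, covs) {
  if (length(coefs) != length(covs))
    stop("maps must share a skeleton (equal lengths)")
  support <- which(coefs != 0)
  if (length(support) == 0)
    return(list(sign_agreement = NA_real_, r = NA_real_, n_nonzero = 0L,
                support = integer(0)))
  agree <- mean(sign(coefs[support]) == sign(covs[support]))
  r <- if (length(support) >= 3 && sd(coefs[support]) > 0 &&
           sd(covs[support]) > 0)
    cor(coefs[support], covs[support]) else NA_real_
  list(sign_agreement = agree, r = r, n_nonzero = length(support),
       support = support)
}
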