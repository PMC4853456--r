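# Probabilistic tract-map post-processing: way-total normalization,
# percentile-fraction thresholding, skeleton intersection, and feature-matrix
# assembly.

#' Normalize a streamline-count tract map by its way-total
#'
#' Divides per-voxel streamline-sample counts by the way-total (the total
#' number of streamline samples not rejected by the exclusion masks), turning
#' counts into visitation probabilities in `[0, 1]`.
#'
#' @param counts non-negative numeric vector (or array) of per-voxel
#'   streamline-sample counts.
#' @param waytotal positive total count; must be at least the maximum voxel
#'   count.
#' @return per-voxel probabilities with the same shape as `counts`.
#' @examples
#' normalize_tract_map(c(0, 2500, 5000), 5000)  # 0, 0.5, 1
#' @export
normalize_tract_map <- function(counts, waytotal) {
  if (any(counts < 0)) stop("streamline counts must be non-negative")
  if (length(waytotal) != 1 || waytotal <= 0)
    stop("degenerate input: waytotal must be a single positive count")
  if (max(counts) > waytotal)
    stop("waytotal must be at least the maximum voxel count")
  counts / waytotal
}

#' Threshold a probability tract map at a fraction of its 95th percentile
#'
#' Retains voxels whose value is at least `fraction` times the 95th
#' percentile of the within-tract intensity distribution. Following the
#' study's convention the defaults are 0.20 for the uncinate fasciculus and
#' 0.40 for the superior longitudinal fasciculus. The percentile is computed
#' by linear interpolation between order statistics (`quantile` type 7) over
#' the strictly positive voxels only -- zero-valued background voxels are not
#' part of the tract distribution. Retention uses a closed threshold (>=), so
#' ties are kept.
#'
#' @param map numeric vector of per-voxel probabilities/intensities.
#' @param fraction threshold fraction in (0, 1].
#' @return logical vector: tract mask membership. The numeric threshold is
#'   attached as attribute `"threshold"`.
#' @export
threshold_tract_map <- function(map, fraction = 0.20) {
  if (!(fraction > 0 && fraction <= 1)) stop("fraction must lie in (0, 1]")
  pos <- map[map > 0]
  if (length(pos) == 0)
    stop("degenerate input: map has no positive voxels")
  thr <- fraction * as.numeric(quantile(pos, 0.95, type = 7, names = FALSE))
  mask <- map >= thr
  attr(mask, "threshold") <- thr
  mask
}

#' Intersect a tract mask with the skeleton
#'
#' Returns the skeleton voxel indices whose coordinates fall inside the mask,
#' in a fixed deterministic order (lexicographic by coordinate). The mask is
#' given as coordinates on the same grid as the skeleton.
#'
#' @param mask_coords integer matrix (voxels x 3) of mask coordinates, or a
#'   logical vector of length `n_voxels` aligned to the skeleton.
#' @param skeleton a `tract_skeleton`.
#' @return integer vector of skeleton voxel indices (1-based), lexicographic
#'   by coordinate; empty (with a warning) if disjoint.
#' @export
intersect_with_skeleton <- function(mask_coords, skeleton) {
  stopifnot(inherits(skeleton, "tract_skeleton"))
  if (is.logical(mask_coords)) {
    if (length(mask_coords) != skeleton$n_voxels)
      stop("alignment error: logical mask length must equal skeleton voxel count")
    idx <- which(mask_coords)
  } else {
    mask_coords <- as.matrix(mask_coords)
    if (ncol(mask_coords) != 3)
      stop("alignment error: mask coordinates must have three columns")
    key <- function(m) paste(m[, 1], m[, 2], m[, 3])
    idx <- which(key(skeleton$coords) %in% key(mask_coords))
  }
  if (length(idx) == 0) {
    warning("mask and skeleton are disjoint; empty voxel list")
    return(integer(0))
  }
  co <- skeleton$coords[idx, , drop = FALSE]
  idx[order(co[, 1], co[, 2], co[, 3])]
}

#' Assemble a subject-by-voxel feature matrix for one DTI metric
#'
#' Entry (i, j) is subject i's metric value at voxel `voxels[j]`; rows follow
#' the cohort's subject order and no imputation is performed.
#'
#' @param cohort a `dti_cohort`.
#' @param voxels integer vector of skeleton voxel indices (columns, in the
#'   given order). Defaults to all skeleton voxels.
#' @param metric one of `"FA"`, `"MD"`, `"AD"`, `"RD"`.
#' @return numeric matrix (subjects x voxels) with subject ids as row names
#'   and the voxel indices as attribute `"voxels"`.
#' @export
assemble_feature_matrix <- function(cohort, voxels = NULL, metric = "MD") {
  stopifnot(inherits(cohort, "dti_cohort"))
  if (!metric %in% names(cohort$features))
    stop("invalid parameter: unknown metric '", metric, "'")
  if (is.null(voxels)) voxels <- seq_len(cohort$skeleton$n_voxels)
  if (length(voxels) == 0)
    stop("degenerate input: empty voxel list gives a 0-column feature matrix")
  if (any(voxels < 1 | voxels > cohort$skeleton$n_voxels))
    stop("voxel indices outside the cohort skeleton")
  X <- cohort$features[[metric]][, voxels, drop = FALSE]
  attr(X, "voxels") <- as.integer(voxels)
  attr(X, "metric") <- metric
  X
}
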