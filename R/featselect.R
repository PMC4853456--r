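# Univariate per-voxel F-score feature selection (Chen & Lin style), always
# computed strictly within a training fold.

#' Per-voxel two-class F-score
#'
#' For each voxel the score is
#' \deqn{F = \frac{(\bar x^+ - \bar x)^2 + (\bar x^- - \bar x)^2}
#'                {s_+^2 + s_-^2}}
#' with class sample variances using the n-1 denominator. The score is
#' non-negative and invariant to affine transforms of the voxel values. If a
#' voxel is constant within both classes the score is 0 when the class means
#' also coincide, and `Inf` when they differ (perfect separation sentinel).
#'
#' @param X subjects x voxels feature matrix.
#' @param y +1/-1 labels, at least two subjects per class.
#' @return numeric vector of per-voxel scores.
#' @export
fscore <- function(X, y) {
  y <- check_labels(y)
  if (sum(y == 1) < 2 || sum(y == -1) < 2)
    stop("at least two subjects per class are required")
  Xp <- X[y == 1, , drop = FALSE]
  Xn <- X[y == -1, , drop = FALSE]
  mp <- colMeans(Xp); mn <- colMeans(Xn); m <- colMeans(X)
  vp <- apply(Xp, 2, var); vn <- apply(Xn, 2, var)
  num <- (mp - m)^2 + (mn - m)^2
  den <- vp + vn
  out <- num / den
  out[den == 0 & num == 0] <- 0
  out[den == 0 & num > 0] <- Inf
  unname(out)
}

#' Retain the top-scoring fraction of voxels
#'
#' Keeps the `ceiling(fraction * V)` highest-scoring voxels (ceiling so a
#' positive fraction never retains zero voxels). Ties are broken toward the
#' lower voxel index, making selection deterministic; retained sets are
#' nested as the fraction grows.
#'
#' @param scores per-voxel scores.
#' @param fraction fraction in (0, 1].
#' @return list with `retained` (voxel indices ordered by decreasing score,
#'   ties by index), `scores`, and `fraction`.
#' @export
select_top_fraction <- function(scores, fraction) {
  if (length(scores) == 0) stop("degenerate input: empty score vector")
  if (!(fraction > 0 && fraction <= 1)) stop("fraction must lie in (0, 1]")
  k <- ceiling(fraction * length(scores))
  ord <- order(-scores, seq_along(scores))
  list(retained = ord[seq_len(k)], scores = scores, fraction = fraction)
}
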