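# Tract skeleton geometry: the voxel grid every map and feature matrix lives on.
#
# A skeleton is a connected set of 1-mm voxels following a smooth curve between
# two end regions ("frontal" and "temporal", after the orbitofrontal and
# anterior temporal terminations of the uncinate fasciculus). Adjacency is
# 26-neighbour connectivity.

#' Construct a tract skeleton from explicit voxel coordinates
#'
#' Builds the 26-connectivity adjacency graph over a set of integer voxel
#' coordinates and labels the two ends of the tract. This is the low-level
#' constructor; [make_skeleton()] generates realistic curved-tube geometry.
#'
#' @param coords integer matrix (voxels x 3) of 0-based 1-mm grid coordinates.
#' @param end_fraction fraction of voxels assigned to each end region
#'   (`0 < end_fraction < 0.5`). Exactly `ceiling(end_fraction * n)` voxels get
#'   each end label, ranked by arc position.
#' @param arc optional numeric vector giving each voxel's position along the
#'   tract in `[0, 1]` (0 = frontal end). If `NULL` it is derived from graph
#'   distance to the two extremal voxels.
#' @param hemisphere `"left"` or `"right"`, metadata only.
#' @return An object of class `tract_skeleton`: a list with elements `coords`
#'   (0-based integer matrix), `edges` (two-column matrix of 1-based voxel
#'   indices, `i < j`), `end_labels` (character, `frontal`/`mid`/`temporal`),
#'   `arc`, `hemisphere`, and `n_voxels`.
#' @export
skeleton_from_coords <- function(coords, end_fraction = 0.15, arc = NULL,
                                 hemisphere = c("right", "left")) {
  hemisphere <- match.arg(hemisphere)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "integer"
  if (ncol(coords) != 3) stop("coords must have three columns")
  n <- nrow(coords)
  if (anyDuplicated(coords) > 0)
    stop("voxel coordinates must be unique")
  if (!(end_fraction > 0 && end_fraction < 0.5))
    stop("end_fraction must lie in (0, 0.5)")
  edges <- neighbour_edges(coords)
  if (is.null(arc)) {
    g <- skeleton_graph_from(edges, n)
    comp <- igraph::components(g)
    if (comp$no == 1) {
      ecc <- igraph::distances(g, v = which.max(igraph::eccentricity(g)))
      d0 <- as.vector(ecc)
      arc <- d0 / max(d0, 1)
    } else {
      # fall back to the dominant coordinate axis for disconnected input
      pc <- stats::prcomp(coords)$x[, 1]
      arc <- (pc - min(pc)) / max(max(pc) - min(pc), 1)
    }
  }
  if (length(arc) != n) stop("arc must have one value per voxel")
  k <- ceiling(end_fraction * n)
  if (2 * k > n)
    stop("n_voxels too small to form two disjoint end regions at this end_fraction")
  ord <- order(arc, coords[, 1], coords[, 2], coords[, 3])
  end_labels <- rep("mid", n)
  end_labels[ord[seq_len(k)]] <- "frontal"
  end_labels[ord[seq.int(n - k + 1, n)]] <- "temporal"
  structure(list(coords = coords, edges = edges, end_labels = end_labels,
                 arc = as.numeric(arc), hemisphere = hemisphere, n_voxels = n),
            class = "tract_skeleton")
}

# 26-connectivity edge list (1-based, i < j), deterministic order.
neighbour_edges <- function(coords) {
  n <- nrow(coords)
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  span <- max(coords) - min(coords) + 3L
  key <- function(m) (m[, 1] + 1L) + span * ((m[, 2] + 1L) + span * (m[, 3] + 1L))
  k0 <- key(coords - min(coords))
  base <- coords - min(coords)
  from <- integer(0); to <- integer(0)
  for (r in seq_len(nrow(off))) {
    kn <- key(sweep(base, 2, -off[r, ], "-"))
    hit <- match(kn, k0)
    ok <- which(!is.na(hit) & hit > seq_len(n))
    from <- c(from, ok); to <- c(to, hit[ok])
  }
  ord <- order(from, to)
  cbind(from = from[ord], to = to[ord])
}

skeleton_graph_from <- function(edges, n) {
  igraph::make_graph(edges = as.vector(t(edges)), n = n, directed = FALSE)
}

#' @noRd
skeleton_graph <- function(skeleton) {
  skeleton_graph_from(skeleton$edges, skeleton$n_voxels)
}

#' Number of connected components of a skeleton's adjacency graph
#' @param skeleton a `tract_skeleton`.
#' @return integer component count (1 for a valid skeleton).
#' @export
skeleton_components <- function(skeleton) {
  igraph::components(skeleton_graph(skeleton))$no
}

#' Generate a curved tract skeleton
#'
#' Voxelizes a smooth 3-D curve into a connected tube of exactly `n_voxels`
#' 1-mm voxels joining a frontal and a temporal end region, emulating the
#' hook-shaped course of the uncinate fasciculus. The default sizes follow the
#' study tract sizes (around 800-1000 skeleton voxels per hemisphere).
#'
#' @param n_voxels number of skeleton voxels (>= 10).
#' @param curvature list with `amplitude` (lateral bow of the curve as a
#'   fraction of its length) and `lift` (out-of-plane bow); both shape
#'   parameters, unitless.
#' @param end_fraction fraction of voxels in each end region.
#' @param seed integer seed controlling the small random perturbation of the
#'   curve's control points; the result is deterministic given `seed`.
#' @param hemisphere `"left"` or `"right"`.
#' @return A `tract_skeleton` (see [skeleton_from_coords()]).
#' @examples
#' sk <- make_skeleton(200, seed = 1)
#' skeleton_components(sk)  # 1
#' table(sk$end_labels)
#' @export
make_skeleton <- function(n_voxels, curvature = list(amplitude = 0.35, lift = 0.2),
                          end_fraction = 0.15, seed = 1,
                          hemisphere = c("right", "left")) {
  hemisphere <- match.arg(hemisphere)
  if (n_voxels < 10) stop("n_voxels must be at least 10")
  if (!(end_fraction > 0 && end_fraction < 0.5))
    stop("end_fraction must lie in (0, 0.5)")
  amp <- curvature$amplitude %||% 0.35
  lift <- curvature$lift %||% 0.2
  # curve length in mm chosen so a tube of modest radius reaches n_voxels
  L <- max(10, round(n_voxels / 9))
  ctrl <- with_seed(child_seed(seed, 1L), {
    jit <- rnorm(6, 0, 0.03)
    rbind(c(0, 0, 0),
          c(L * (0.35 + jit[1]), L * (amp + jit[2]), L * (0.3 * lift + jit[3])),
          c(L * (0.65 + jit[4]), L * (amp + jit[5]), L * (lift + jit[6])),
          c(L, 0, L * lift * 0.5))
  })
  tt <- seq(0, 1, length.out = 8 * L)
  bez <- bezier_points(ctrl, tt)
  # grow the tube radius until the candidate voxel set is large enough
  r <- max(1, sqrt(n_voxels / (pi * L)))
  repeat {
    cand <- tube_voxels(bez, tt, r)
    if (nrow(cand$coords) >= n_voxels) break
    r <- r + 0.25
  }
  sel <- pick_connected_subset(cand, n_voxels)
  coords <- cand$coords[sel, , drop = FALSE]
  coords <- sweep(coords, 2, apply(coords, 2, min))  # 0-based, nonneg grid
  skeleton_from_coords(coords, end_fraction = end_fraction,
                       arc = cand$arc[sel], hemisphere = hemisphere)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# cubic Bezier through 4 control points
bezier_points <- function(P, t) {
  b <- cbind((1 - t)^3, 3 * t * (1 - t)^2, 3 * t^2 * (1 - t), t^3)
  b %*% P
}

# integer voxels within distance r of the sampled curve, with the arc position
# and distance of the nearest sample
tube_voxels <- function(bez, tt, r) {
  lo <- floor(apply(bez, 2, min)) - ceiling(r)
  hi <- ceiling(apply(bez, 2, max)) + ceiling(r)
  gx <- seq(lo[1], hi[1]); gy <- seq(lo[2], hi[2]); gz <- seq(lo[3], hi[3])
  grid <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  # nearest curve sample per voxel, blocked to bound memory
  nv <- nrow(grid)
  dmin <- rep(Inf, nv); amin <- numeric(nv)
  block <- 20000L
  for (s in seq(1, nv, by = block)) {
    idx <- s:min(s + block - 1L, nv)
    d2 <- outer(rowSums(grid[idx, , drop = FALSE]^2), rowSums(bez^2), "+") -
      2 * grid[idx, , drop = FALSE] %*% t(bez)
    j <- max.col(-d2, ties.method = "first")
    dmin[idx] <- sqrt(pmax(d2[cbind(seq_along(idx), j)], 0))
    amin[idx] <- tt[j]
  }
  keep <- dmin <= r
  list(coords = grid[keep, , drop = FALSE], dist = dmin[keep], arc = amin[keep])
}

# Keep exactly n voxels nearest the curve while preserving 26-connectivity:
# start from the nearest-n set, then repair by swapping in unused voxels
# adjacent to the main component for the most distant voxels of minor
# components.
pick_connected_subset <- function(cand, n) {
  ordc <- order(cand$dist, cand$coords[, 1], cand$coords[, 2], cand$coords[, 3])
  sel <- sort(ordc[seq_len(n)])
  for (attempt in 1:50) {
    co <- cand$coords[sel, , drop = FALSE]
    ed <- neighbour_edges(co)
    comp <- igraph::components(skeleton_graph_from(ed, n))
    if (comp$no == 1) return(sel)
    main <- which.max(comp$csize)
    minor <- which(comp$membership != main)
    # drop the minor-component voxel farthest from the curve ...
    drop_local <- minor[which.max(cand$dist[sel][minor])]
    keep <- sel[-drop_local]
    # ... and add the unused voxel nearest the curve that touches the main set
    unused <- setdiff(seq_along(cand$dist), sel)
    main_co <- cand$coords[sel[comp$membership == main], , drop = FALSE]
    touching <- vapply(unused, function(u) {
      d <- abs(sweep(main_co, 2, cand$coords[u, ], "-"))
      any(apply(d, 1, max) <= 1)
    }, logical(1))
    cand_add <- unused[touching]
    if (length(cand_add) == 0) stop("could not form a connected skeleton tube")
    add <- cand_add[which.min(cand$dist[cand_add])]
    sel <- sort(c(keep, add))
  }
  stop("could not form a connected skeleton tube")
}

#' Sparse gradient (edge-difference) operator of a skeleton
#'
#' One row per adjacency edge with +1/-1 on the edge's endpoints, mapping a
#' per-voxel coefficient vector to per-edge differences. This is the linear
#' operator inside the total-variation penalty: a constant map is sent to the
#' zero vector, and on a connected skeleton the operator has rank V - 1.
#'
#' @param skeleton a `tract_skeleton`.
#' @return a `dgCMatrix` of dimension (edges x voxels).
#' @export
build_tract_gradient <- function(skeleton) {
  m <- nrow(skeleton$edges)
  Matrix::sparseMatrix(i = rep(seq_len(m), 2),
                       j = c(skeleton$edges[, 1], skeleton$edges[, 2]),
                       x = rep(c(1, -1), each = m),
                       dims = c(m, skeleton$n_voxels))
}

#' @export
print.tract_skeleton <- function(x, ...) {
  cat(sprintf("tract_skeleton: %d voxels, %d edges, %s hemisphere\n",
              x$n_voxels, nrow(x$edges), x$hemisphere))
  cat(sprintf("  end regions: %d frontal, %d temporal, %d mid\n",
              sum(x$end_labels == "frontal"), sum(x$end_labels == "temporal"),
              sum(x$end_labels == "mid")))
  invisible(x)
}
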