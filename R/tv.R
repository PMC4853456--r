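# Structured sparse total-variation logistic regression, solved by ADMM.
#
#   minimize  (1/n) sum_i log(1 + exp(-y_i (b0 + x_i' beta)))
#             + lambda1 ||beta||_1 + lambda_tv sum_edges |beta_u - beta_v|
#
# The TV term is anisotropic (sum of absolute differences over skeleton
# adjacency edges) so the z-update splits into elementwise soft-thresholding.
# Splitting: z1 = beta, z2 = D beta with D the edge-difference operator;
# scaled dual u; the beta-step is a smooth logistic + quadratic minimization
# solved by L-BFGS-B with warm starts. The penalty parameter rho starts at 1
# and is rebalanced from the primal/dual residual ratio.

#' Edge-difference operator restricted to a voxel subset
#'
#' Keeps the skeleton adjacency edges whose both endpoints are among
#' `voxels`, re-indexed to the subset's column order. Used when feature
#' selection retains only part of the skeleton inside a training fold.
#'
#' @param skeleton a `tract_skeleton`.
#' @param voxels integer vector of retained skeleton voxel indices.
#' @return sparse edge x voxel matrix with +1/-1 entries.
#' @export
subgraph_gradient <- function(skeleton, voxels) {
  idx <- match(seq_len(skeleton$n_voxels), voxels)
  e1 <- idx[skeleton$edges[, 1]]
  e2 <- idx[skeleton$edges[, 2]]
  keep <- !is.na(e1) & !is.na(e2)
  m <- sum(keep)
  if (m == 0)
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(0, length(voxels))))
  Matrix::sparseMatrix(i = rep(seq_len(m), 2), j = c(e1[keep], e2[keep]),
                       x = rep(c(1, -1), each = m),
                       dims = c(m, length(voxels)))
}

#' Train a total-variation penalized logistic regression classifier
#'
#' @param X subjects x voxels feature matrix.
#' @param y +1/-1 labels.
#' @param D edge-difference operator (rows = edges, columns = features), as
#'   from [build_tract_gradient()] or [subgraph_gradient()]; a
#'   `tract_skeleton` may be passed instead when all skeleton voxels are
#'   features.
#' @param spec a `classifier_spec` with `family = "tv_lrc"` carrying
#'   `lambda1` and `lambda_tv`.
#' @param rho initial ADMM penalty parameter.
#' @param eps_abs,eps_rel absolute/relative residual tolerances.
#' @param max_iter ADMM iteration cap.
#' @return a `tract_model`; `beta` is the consensus (sparse) variable, and
#'   `residuals` reports the exit primal/dual residuals with a convergence
#'   flag. Warns and returns the partial solution on non-convergence.
#' @export
train_tv_lrc <- function(X, y, D, spec = classifier_spec("tv_lrc"),
                         rho = 1, eps_abs = 1e-9, eps_rel = 1e-7,
                         max_iter = 5000) {
  y <- check_labels(y, require_both = FALSE)
  if (spec$family != "tv_lrc") stop("spec$family must be 'tv_lrc'")
  if (!all(is.finite(X))) stop("non-finite feature values")
  X <- as.matrix(X)
  p <- ncol(X)
  if (inherits(D, "tract_skeleton")) {
    if (D$n_voxels != p)
      stop("alignment error: skeleton voxel count must match feature columns")
    D <- build_tract_gradient(D)
  }
  if (is.null(D)) stop("tv_lrc requires the edge-difference operator D")
  D <- methods::as(D, "CsparseMatrix")
  if (ncol(D) != p) stop("alignment error: ncol(D) must match feature columns")
  sc <- if (spec$standardize) standardizer(X) else
    list(mu = rep(0, p), sd = rep(1, p))
  Z <- apply_standardizer(X, sc)
  n <- nrow(Z); m <- nrow(D)
  lambda1 <- spec$lambda1; lambda_tv <- spec$lambda_tv

  A <- rbind(Matrix::Diagonal(p), D)
  At <- Matrix::t(A)
  beta0 <- 0; beta <- rep(0, p)
  z <- rep(0, p + m); u <- rep(0, p + m)
  obj_beta <- function(b0, b)
    penalized_objective(b0, b, Z, y, lambda1, alpha = 1, lambda_tv = lambda_tv,
                        D = D)
  trace <- obj_beta(beta0, beta)
  converged <- FALSE
  r_norm <- s_norm <- NA_real_
  for (it in seq_len(max_iter)) {
    # beta-step: smooth logistic + quadratic coupling, warm-started L-BFGS-B
    target <- z - u
    fn <- function(th) {
      b0 <- th[1]; b <- th[-1]
      Ab <- as.vector(A %*% b)
      mean(logistic_loss(y * (b0 + as.vector(Z %*% b)))) +
        rho / 2 * sum((Ab - target)^2)
    }
    gr <- function(th) {
      b0 <- th[1]; b <- th[-1]
      eta <- b0 + as.vector(Z %*% b)
      w <- -y * plogis(-y * eta) / n
      resid <- as.vector(A %*% b) - target
      c(sum(w), as.vector(crossprod(Z, w)) + rho * as.vector(At %*% resid))
    }
    opt <- optim(c(beta0, beta), fn, gr, method = "L-BFGS-B",
                 control = list(maxit = 500, factr = 1e4))
    beta0 <- opt$par[1]; beta <- opt$par[-1]
    Ab <- as.vector(A %*% beta)
    # z-step: elementwise soft-thresholding; u-step: scaled dual ascent
    z_old <- z
    v <- Ab + u
    z <- c(soft_threshold(v[seq_len(p)], lambda1 / rho),
           if (m > 0) soft_threshold(v[p + seq_len(m)], lambda_tv / rho))
    u <- u + Ab - z
    r <- Ab - z
    s <- rho * as.vector(At %*% (z - z_old))
    r_norm <- sqrt(sum(r^2)); s_norm <- sqrt(sum(s^2))
    eps_pri <- sqrt(p + m) * eps_abs +
      eps_rel * max(sqrt(sum(Ab^2)), sqrt(sum(z^2)))
    eps_dua <- sqrt(p) * eps_abs + eps_rel * rho * sqrt(sum(as.vector(At %*% u)^2))
    trace <- c(trace, obj_beta(beta0, beta))
    if (r_norm <= eps_pri && s_norm <= eps_dua) { converged <- TRUE; break }
    # residual balancing keeps primal and dual progress comparable
    if (r_norm > 10 * s_norm) { rho <- rho * 2; u <- u / 2 }
    else if (s_norm > 10 * r_norm) { rho <- rho / 2; u <- u * 2 }
  }
  if (!converged)
    warning(sprintf(paste0("TV LRC ADMM did not converge within %d iterations ",
                           "(primal residual %.2e, dual %.2e); returning the ",
                           "partial solution"), max_iter, r_norm, s_norm))
  beta_out <- z[seq_len(p)]  # consensus variable carries the exact sparsity
  structure(list(spec = spec, family = "tv_lrc", scaling = sc,
                 beta0 = beta0, beta = beta_out,
                 objective = penalized_objective(beta0, beta_out, Z, y, lambda1,
                                                 alpha = 1,
                                                 lambda_tv = lambda_tv, D = D),
                 trace = trace, converged = converged,
                 residuals = c(primal = r_norm, dual = s_norm),
                 n_features = p),
            class = "tract_model")
}
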