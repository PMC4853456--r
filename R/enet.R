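# ElasticNet-penalized logistic regression, solved by accelerated proximal
# gradient (FISTA with gradient-based adaptive restart). The objective is
#
#   (1/n) sum_i log(1 + exp(-y_i (b0 + x_i' beta)))
#     + lambda1 * [ alpha ||beta||_1 + (1 - alpha)/2 ||beta||_2^2 ]
#
# with the intercept unpenalized. The ridge part joins the smooth term; the
# lasso part enters through soft-thresholding.

#' Train an ElasticNet logistic regression classifier
#'
#' @param X subjects x voxels feature matrix.
#' @param y +1/-1 labels.
#' @param spec a `classifier_spec` with `family = "enet_lrc"` carrying
#'   `lambda1` and `alpha`.
#' @param max_iter iteration cap; with `lambda1 = 0` on separable data the
#'   optimum is at infinity and the cap triggers a non-convergence warning by
#'   design.
#' @param tol relative objective-change tolerance.
#' @return a `tract_model` with `beta0`, sparse `beta` (standardized scale;
#'   see [coef.tract_model()] for the raw scale), the objective trace, and a
#'   convergence flag.
#' @export
train_enet_lrc <- function(X, y, spec = classifier_spec("enet_lrc"),
                           max_iter = 20000, tol = 1e-12) {
  y <- check_labels(y, require_both = FALSE)
  if (spec$family != "enet_lrc") stop("spec$family must be 'enet_lrc'")
  if (!all(is.finite(X))) stop("non-finite feature values")
  X <- as.matrix(X)
  sc <- if (spec$standardize) standardizer(X) else
    list(mu = rep(0, ncol(X)), sd = rep(1, ncol(X)))
  Z <- apply_standardizer(X, sc)
  fit <- fista_logistic(Z, y, lambda_l1 = spec$lambda1 * spec$alpha,
                        lambda_l2 = spec$lambda1 * (1 - spec$alpha),
                        max_iter = max_iter, tol = tol)
  if (!fit$converged)
    warning("ElasticNet LRC did not converge within the iteration cap; ",
            "returning the partial solution")
  structure(list(spec = spec, family = "enet_lrc", scaling = sc,
                 beta0 = fit$beta0, beta = fit$beta,
                 objective = fit$objective, trace = fit$trace,
                 converged = fit$converged, n_features = ncol(X)),
            class = "tract_model")
}

# FISTA on (smooth: mean logloss + l2/2 ||beta||^2, prox: l1). The intercept
# rides along in the smooth part with no penalty.
fista_logistic <- function(Z, y, lambda_l1, lambda_l2, max_iter, tol) {
  n <- nrow(Z); p <- ncol(Z)
  # Lipschitz bound for the smooth gradient: ||[1 Z]||_2^2 / (4n) + l2
  Zi <- cbind(1, Z)
  L <- spectral_norm_sq(Zi) / (4 * n) + lambda_l2
  obj <- function(b0, b) {
    mean(logistic_loss(y * (b0 + as.vector(Z %*% b)))) +
      lambda_l1 * sum(abs(b)) + lambda_l2 / 2 * sum(b^2)
  }
  grad <- function(b0, b) {
    eta <- b0 + as.vector(Z %*% b)
    w <- -y * plogis(-y * eta) / n
    list(g0 = sum(w), g = as.vector(crossprod(Z, w)) + lambda_l2 * b)
  }
  b0 <- 0; b <- rep(0, p)
  v0 <- b0; v <- b
  tmom <- 1
  f_prev <- obj(b0, b)
  trace <- f_prev
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    g <- grad(v0, v)
    b0_new <- v0 - g$g0 / L
    b_new <- soft_threshold(v - g$g / L, lambda_l1 / L)
    t_new <- (1 + sqrt(1 + 4 * tmom^2)) / 2
    # gradient-based adaptive restart
    if (sum((v - b_new) * (b_new - b)) + (v0 - b0_new) * (b0_new - b0) > 0) {
      t_new <- 1
      v0 <- b0_new; v <- b_new
    } else {
      mom <- (tmom - 1) / t_new
      v0 <- b0_new + mom * (b0_new - b0)
      v <- b_new + mom * (b_new - b)
    }
    b0 <- b0_new; b <- b_new; tmom <- t_new
    if (it %% 10 == 0 || it == max_iter) {
      f <- obj(b0, b)
      trace <- c(trace, f)
      if (abs(f_prev - f) <= tol * max(1, abs(f))) { converged <- TRUE; break }
      f_prev <- f
    }
  }
  list(beta0 = b0, beta = b, objective = obj(b0, b), trace = trace,
       converged = converged)
}

# squared spectral norm via power iteration on t(A) %*% A
spectral_norm_sq <- function(A, iter = 50) {
  G <- crossprod(A)
  v <- rep(1, ncol(G)) / sqrt(ncol(G))
  lam <- 0
  for (i in seq_len(iter)) {
    w <- as.vector(G %*% v)
    nw <- sqrt(sum(w^2))
    if (nw == 0) return(0)
    v <- w / nw
    lam <- nw
  }
  lam * 1.01  # small safety margin keeps the step a valid majorizer
}
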