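# Classifier families: kernel SVM (compact SMO solver), ElasticNet logistic
# regression (FISTA), and structured sparse total-variation logistic
# regression (ADMM). All share the convention that a higher decision score
# means more +1 (athlete)-like, and sign ties resolve to +1.

#' Classifier specification
#'
#' @param family `"svm"`, `"enet_lrc"` or `"tv_lrc"`.
#' @param kernel SVM kernel: `"linear"`, `"polynomial"` or `"rbf"`.
#' @param cost SVM soft-margin cost C (> 0).
#' @param gamma kernel scale for RBF/polynomial; default `NULL` means `1/p`
#'   at training time.
#' @param degree polynomial degree (integer >= 1); fixed default 3.
#' @param coef0 polynomial offset; default 1.
#' @param lambda1 sparsity weight (>= 0) of the penalized logistic families.
#' @param alpha ElasticNet mixing in `[0, 1]` (1 = pure lasso).
#' @param lambda_tv total-variation weight (>= 0), `tv_lrc` only.
#' @param standardize per-voxel z-scoring with training-fold mean/SD,
#'   applied identically to test subjects; default `TRUE`.
#' @return an object of class `classifier_spec`.
#' @export
classifier_spec <- function(family = c("svm", "enet_lrc", "tv_lrc"),
                            kernel = c("rbf", "linear", "polynomial"),
                            cost = 1, gamma = NULL, degree = 3, coef0 = 1,
                            lambda1 = 0.1, alpha = 0.5, lambda_tv = 0.1,
                            standardize = TRUE) {
  family <- match.arg(family)
  kernel <- match.arg(kernel)
  if (cost <= 0) stop("cost must be positive")
  if (!is.null(gamma) && gamma <= 0) stop("gamma must be positive")
  if (degree < 1 || degree != round(degree)) stop("degree must be a positive integer")
  if (lambda1 < 0 || lambda_tv < 0) stop("penalty weights must be non-negative")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  structure(list(family = family, kernel = kernel, cost = cost, gamma = gamma,
                 degree = degree, coef0 = coef0, lambda1 = lambda1,
                 alpha = alpha, lambda_tv = lambda_tv,
                 standardize = isTRUE(standardize)),
            class = "classifier_spec")
}

kernel_code <- function(kernel) {
  match(kernel, c("linear", "polynomial", "rbf")) - 1L
}

#' Train a kernel SVM
#'
#' Soft-margin C-SVC solved by sequential minimal optimization on the dual.
#' Features are z-scored with training means/SDs when `spec$standardize`.
#'
#' @param X subjects x voxels feature matrix.
#' @param y +1/-1 labels (at least one subject per class).
#' @param spec a `classifier_spec` with `family = "svm"`.
#' @return a `tract_model`.
#' @export
train_svm <- function(X, y, spec = classifier_spec("svm")) {
  y <- check_labels(y)
  if (spec$family != "svm") stop("spec$family must be 'svm'")
  if (!all(is.finite(X))) stop("non-finite feature values")
  X <- as.matrix(X)
  sc <- if (spec$standardize) standardizer(X) else
    list(mu = rep(0, ncol(X)), sd = rep(1, ncol(X)))
  Z <- apply_standardizer(X, sc)
  gamma <- spec$gamma %||% (1 / ncol(X))
  fit <- svm_fit_cpp(Z, y, kernel_code(spec$kernel), spec$cost, gamma,
                     spec$degree, spec$coef0)
  structure(list(spec = spec, family = "svm", scaling = sc,
                 Xtrain = Z, ya = fit$ya, b = fit$b, gamma = gamma,
                 converged = fit$converged, n_features = ncol(X)),
            class = "tract_model")
}

#' Decision scores of a trained model
#'
#' Higher score means more +1 (athlete)-like; the predicted label is the
#' sign of the score with ties resolved to +1. For linear families the score
#' is `intercept + sum(coefficient * feature)` after the model's stored
#' standardization.
#'
#' @param model a `tract_model`.
#' @param X feature matrix whose columns match the training features.
#' @return numeric vector of per-subject scores.
#' @export
decision_scores <- function(model, X) {
  stopifnot(inherits(model, "tract_model"))
  X <- as.matrix(X)
  if (ncol(X) != model$n_features)
    stop("alignment error: feature columns do not match the trained model")
  Z <- apply_standardizer(X, model$scaling)
  if (model$family == "svm") {
    as.vector(svm_decision_cpp(model$Xtrain, model$ya, model$b, Z,
                               kernel_code(model$spec$kernel), model$gamma,
                               model$spec$degree, model$spec$coef0))
  } else {
    as.vector(model$beta0 + Z %*% model$beta)
  }
}

#' Predicted labels (+1/-1) from decision scores
#' @param model a `tract_model`.
#' @param X feature matrix.
#' @return integer vector of +1/-1 labels; a score of exactly 0 gives +1.
#' @export
predict_labels <- function(model, X) {
  s <- decision_scores(model, X)
  ifelse(s >= 0, 1L, -1L)
}

#' Per-voxel coefficients of a linear model on the original feature scale
#'
#' Undoes the internal standardization so coefficients multiply raw metric
#' values. SVM models (non-linear in general) are rejected.
#' @param object a `tract_model` of a linear family.
#' @param ... unused.
#' @return list with `intercept` and per-voxel `coefficients`.
#' @export
coef.tract_model <- function(object, ...) {
  if (object$family == "svm")
    stop("coefficient maps are defined for the linear families only")
  beta_raw <- object$beta / object$scaling$sd
  list(intercept = object$beta0 - sum(object$beta * object$scaling$mu /
                                        object$scaling$sd),
       coefficients = beta_raw)
}

#' Train a classifier of any family
#'
#' Dispatches to [train_svm()], [train_enet_lrc()] or [train_tv_lrc()].
#' @param X feature matrix; @param y +1/-1 labels.
#' @param spec a `classifier_spec`.
#' @param D edge-difference operator (required for `tv_lrc`).
#' @return a `tract_model`.
#' @export
train_classifier <- function(X, y, spec, D = NULL) {
  switch(spec$family,
         svm = train_svm(X, y, spec),
         enet_lrc = train_enet_lrc(X, y, spec),
         tv_lrc = train_tv_lrc(X, y, D, spec))
}

#' @export
print.tract_model <- function(x, ...) {
  cat(sprintf("tract_model: %s", x$family))
  if (x$family == "svm")
    cat(sprintf(" (%s kernel, C=%g, gamma=%g)", x$spec$kernel, x$spec$cost,
                x$gamma))
  else
    cat(sprintf(" (lambda1=%g, alpha=%g, lambda_tv=%g); %d non-zero of %d",
                x$spec$lambda1, x$spec$alpha, x$spec$lambda_tv,
                sum(x$beta != 0), length(x$beta)))
  cat(sprintf("; converged: %s\n", x$converged))
  invisible(x)
}
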