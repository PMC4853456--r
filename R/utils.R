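# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so library code never clobbers
#' the global stream.
#' @noRd
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Counter-based seed fan-out
#'
#' Derives a child seed from a base seed and a stream counter so that each
#' subject (or permutation block) gets an independent, individually
#' reproducible stream. Kept inside 32-bit integer range.
#' @noRd
child_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(counter) * 7919) %% 2147483629L)
}

#' Numerically stable logistic loss log(1 + exp(-t))
#' @noRd
logistic_loss <- function(t) pmax(-t, 0) + log1p(exp(-abs(t)))

#' Soft-thresholding operator, the proximal map of the absolute value
#' @noRd
soft_threshold <- function(x, lambda) sign(x) * pmax(abs(x) - lambda, 0)

#' Validate a +1/-1 label vector
#' @noRd
check_labels <- function(y, require_both = TRUE) {
  if (!is.numeric(y) || !all(y %in% c(-1, 1)))
    stop("labels must be coded -1 (control) / +1 (athlete)", call. = FALSE)
  if (require_both && (all(y == 1) || all(y == -1)))
    stop("both classes must be present", call. = FALSE)
  invisible(as.numeric(y))
}

#' Penalized logistic objective shared by the sparse linear families
#'
#' mean logistic loss + lambda1 * (alpha * ||beta||_1 + (1-alpha)/2 * ||beta||_2^2)
#'   + lambda_tv * sum_e |(D beta)_e|
#' The intercept is never penalized.
#' @noRd
penalized_objective <- function(beta0, beta, X, y, lambda1, alpha = 1,
                                lambda_tv = 0, D = NULL) {
  eta <- beta0 + as.vector(X %*% beta)
  obj <- mean(logistic_loss(y * eta)) +
    lambda1 * (alpha * sum(abs(beta)) + (1 - alpha) / 2 * sum(beta^2))
  if (!is.null(D) && lambda_tv > 0)
    obj <- obj + lambda_tv * sum(abs(as.vector(D %*% beta)))
  obj
}

#' Training-fold standardization parameters
#'
#' Per-column mean and SD computed on the training rows only; zero-SD columns
#' get SD 1 so constant voxels pass through unscaled rather than dividing by 0.
#' @noRd
standardizer <- function(X) {
  mu <- colMeans(X)
  s <- apply(X, 2, sd)
  s[!is.finite(s) | s == 0] <- 1
  list(mu = mu, sd = s)
}

#' @noRd
apply_standardizer <- function(X, sc) {
  sweep(sweep(X, 2, sc$mu, "-"), 2, sc$sd, "/")
}
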