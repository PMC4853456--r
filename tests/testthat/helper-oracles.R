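# Independent oracles used across the suite. These deliberately do not call
# package internals: the penalized objective, the convex solver, the AUC pair
# count and the TFCE discrete sum are re-derived from their definitions.

# stable log(1 + exp(-t))
ref_logloss <- function(t) pmax(-t, 0) + log1p(exp(-abs(t)))

# reference penalized logistic objective (mean loss + ElasticNet + TV)
ref_objective <- function(b0, b, X, y, lambda1, alpha = 1, lambda_tv = 0,
                          D = NULL) {
  eta <- b0 + as.vector(X %*% b)
  val <- mean(ref_logloss(y * eta)) +
    lambda1 * (alpha * sum(abs(b)) + (1 - alpha) / 2 * sum(b^2))
  if (!is.null(D) && lambda_tv > 0)
    val <- val + lambda_tv * sum(abs(as.vector(D %*% b)))
  val
}

# Generic convex-optimization oracle: log-barrier interior point
# (constrOptim) on the epigraph formulation of the L1/TV terms. Constraint
# offsets are relaxed by 1e-10 because the optimum sits exactly on the
# epigraph boundary where the barrier is undefined; a ladder of barrier
# scales and starts is tried and the best feasible objective returned once
# two settings agree.
convex_oracle <- function(X, y, lambda1, alpha = 1, lambda_tv = 0, D = NULL,
                          agree_tol = 1e-9) {
  n <- nrow(X); p <- ncol(X)
  useD <- !is.null(D) && lambda_tv > 0
  m <- if (useD) nrow(D) else 0
  fn <- function(th) {
    b0 <- th[1]; b <- th[2:(p + 1)]; s <- th[(p + 2):(2 * p + 1)]
    tt <- if (m) th[(2 * p + 2):(2 * p + 1 + m)] else numeric(0)
    eta <- b0 + as.vector(X %*% b)
    mean(ref_logloss(y * eta)) + lambda1 * alpha * sum(s) +
      lambda1 * (1 - alpha) / 2 * sum(b^2) + lambda_tv * sum(tt)
  }
  gr <- function(th) {
    b0 <- th[1]; b <- th[2:(p + 1)]
    eta <- b0 + as.vector(X %*% b)
    w <- -y * plogis(-y * eta) / n
    c(sum(w), as.vector(crossprod(X, w)) + lambda1 * (1 - alpha) * b,
      rep(lambda1 * alpha, p), rep(lambda_tv, m))
  }
  ui <- cbind(0, rbind(-diag(p), diag(p)), rbind(diag(p), diag(p)))
  if (m) {
    Dm <- as.matrix(D)
    ui <- cbind(ui, matrix(0, 2 * p, m))
    ui <- rbind(ui, cbind(0, rbind(-Dm, Dm), matrix(0, 2 * m, p),
                          rbind(diag(m), diag(m))))
  }
  starts <- list(c(0, rep(0, p), rep(0.5, p), if (m) rep(0.5, m)),
                 c(0, rep(0, p), rep(2, p), if (m) rep(2, m)))
  vals <- c(); best <- NULL
  for (mu in c(1e-7, 1e-6, 1e-5)) for (eps in c(1e-10, 1e-8))
    for (th0 in starts) {
      res <- try(constrOptim(th0, fn, gr, ui = ui, ci = rep(-eps, nrow(ui)),
                             mu = mu, outer.iterations = 250,
                             outer.eps = 1e-11, method = "BFGS",
                             control = list(maxit = 2500, reltol = 1e-14)),
                 silent = TRUE)
      if (!inherits(res, "try-error")) {
        b0 <- res$par[1]; b <- res$par[2:(p + 1)]
        v <- ref_objective(b0, b, X, y, lambda1, alpha, lambda_tv, D)
        if (is.null(best) || v < best$value)
          best <- list(b0 = b0, b = b, value = v)
        vals <- c(vals, v)
        if (sum(abs(vals - best$value) < agree_tol) >= 2) return(best)
      }
    }
  if (is.null(best)) stop("convex oracle failed on all barrier settings")
  best
}

# Mann-Whitney pair-counting AUC (ties count 1/2)
pair_count_auc <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == -1]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Discrete TFCE sum for a map with clusters enumerated by brute force
# (depth-first search over the edge list), independent of the package's
# union-find implementation.
brute_tfce <- function(values, edges, E, H, dh) {
  V <- length(values)
  out <- numeric(V)
  side <- function(v) {
    res <- numeric(V)
    top <- max(v)
    if (top <= 0) return(res)
    for (h in seq(dh, top + dh / 2, by = dh)) {
      if (h > top + 1e-12) break
      alive <- which(v >= h)
      if (!length(alive)) next
      # components by repeated DFS
      unvisited <- rep(TRUE, V); unvisited[-alive] <- FALSE
      for (s in alive) {
        if (!unvisited[s]) next
        comp <- c(); stack <- s; unvisited[s] <- FALSE
        while (length(stack)) {
          cur <- stack[length(stack)]; stack <- stack[-length(stack)]
          comp <- c(comp, cur)
          nb <- c(edges[edges[, 1] == cur, 2], edges[edges[, 2] == cur, 1])
          nb <- nb[unvisited[nb]]
          unvisited[nb] <- FALSE
          stack <- c(stack, nb)
        }
        res[comp] <- res[comp] + length(comp)^E * h^H * dh
      }
    }
    res
  }
  side(pmax(values, 0)) - side(pmax(-values, 0))
}

# chain-graph edge-difference operator
chain_gradient <- function(p) {
  m <- p - 1
  Matrix::sparseMatrix(i = rep(seq_len(m), 2), j = c(seq_len(m), 2:p),
                       x = rep(c(1, -1), each = m), dims = c(m, p))
}
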