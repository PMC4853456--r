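# ElasticNet (FISTA) and total-variation (ADMM) logistic regression against
# independent oracles: glmnet and a generic convex solver.

test_that("ElasticNet objective matches glmnet and the convex oracle", {
  skip_if_not_installed("glmnet")
  set.seed(11)
  for (i in 1:4) {
    n <- sample(8:16, 1); p <- sample(4:12, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- rep(c(1, -1), length.out = n)[sample(n)]
    lam <- runif(1, 0.05, 0.3); al <- runif(1)
    sp <- classifier_spec("enet_lrc", lambda1 = lam, alpha = al,
                          standardize = FALSE)
    m <- train_enet_lrc(X, y, sp)
    mine <- ref_objective(m$beta0, m$beta, X, y, lam, al)
    g <- suppressWarnings(glmnet::glmnet(X, factor(y, levels = c(-1, 1)), family = "binomial",
                        alpha = al, lambda = lam, standardize = FALSE,
                        thresh = 1e-16, maxit = 1e6))
    ref <- ref_objective(as.numeric(g$a0), as.numeric(g$beta), X, y, lam, al)
    expect_lt(mine, ref + 1e-6)
    expect_lt(abs(mine - ref), 1e-6)
  }
})

test_that("full shrinkage leaves only the class-balance intercept", {
  pr <- gaussian_problem(12, 5, seed = 12)
  m <- train_enet_lrc(pr$X, pr$y,
                      classifier_spec("enet_lrc", lambda1 = 1e6, alpha = 1))
  expect_true(all(m$beta == 0))
  expect_equal(m$beta0, log(sum(pr$y == 1) / sum(pr$y == -1)), tolerance = 1e-8)
})

test_that("unpenalized separable logistic regression hits the iteration cap", {
  X <- matrix(c(-2, -1, 1, 2), ncol = 1)
  y <- c(-1, -1, 1, 1)
  expect_warning(
    m <- train_enet_lrc(X, y, classifier_spec("enet_lrc", lambda1 = 0),
                        max_iter = 300),
    "did not converge")
  expect_false(m$converged)
})

test_that("TV-LRC matches the convex oracle and its closed-form limits", {
  set.seed(13)
  p <- 6
  D <- chain_gradient(p)
  for (i in 1:3) {
    n <- 8
    X <- matrix(rnorm(n * p), n, p)
    y <- rep(c(1, -1), each = 4)[sample(n)]
    lam1 <- runif(1, 0.02, 0.2); ltv <- runif(1, 0.02, 0.2)
    m <- train_tv_lrc(X, y, D, classifier_spec("tv_lrc", lambda1 = lam1,
                                               lambda_tv = ltv,
                                               standardize = FALSE))
    o <- convex_oracle(X, y, lam1, 1, ltv, D)
    expect_lt(abs(m$objective - o$value), 1e-5)
    expect_true(m$converged)
  }
  # lambda_tv -> large forces constant coefficients on a chain
  X <- matrix(rnorm(10 * p), 10, p)
  y <- rep(c(1, -1), each = 5)
  mbig <- train_tv_lrc(X, y, D, classifier_spec("tv_lrc", lambda1 = 1e-3,
                                                lambda_tv = 100,
                                                standardize = FALSE))
  expect_lt(diff(range(mbig$beta)), 1e-4)
})

test_that("at zero TV weight the TV-LRC equals the pure-lasso ElasticNet", {
  pr <- gaussian_problem(10, 6, seed = 14)
  D <- chain_gradient(6)
  m_tv <- train_tv_lrc(pr$X, pr$y, D,
                       classifier_spec("tv_lrc", lambda1 = 0.05,
                                       lambda_tv = 0, standardize = FALSE))
  m_en <- train_enet_lrc(pr$X, pr$y,
                         classifier_spec("enet_lrc", lambda1 = 0.05,
                                         alpha = 1, standardize = FALSE))
  expect_lt(max(abs(m_tv$beta - m_en$beta)), 1e-4)
  expect_lt(abs(m_tv$beta0 - m_en$beta0), 1e-4)
})

test_that("coefficients vary continuously along a TV path", {
  pr <- gaussian_problem(12, 6, seed = 15)
  D <- chain_gradient(6)
  path <- sapply(10^seq(-3, 0, length.out = 10), function(ltv) {
    train_tv_lrc(pr$X, pr$y, D,
                 classifier_spec("tv_lrc", lambda1 = 0.02, lambda_tv = ltv,
                                 standardize = FALSE))$beta
  })
  # no sign flips of large coefficients between neighbouring grid points
  for (j in seq_len(ncol(path) - 1)) {
    big <- abs(path[, j]) > 0.05
    expect_true(all(sign(path[big, j]) == sign(path[big, j + 1]) |
                      abs(path[big, j + 1]) < 0.05))
  }
})

test_that("prediction is invariant to training-subject order for all families", {
  pr <- gaussian_problem(12, 5, seed = 16)
  probe <- matrix(rnorm(3 * 5), 3, 5)
  perm <- sample(12)
  D <- chain_gradient(5)
  specs <- list(classifier_spec("svm", kernel = "rbf", gamma = 0.3),
                classifier_spec("enet_lrc", lambda1 = 0.05),
                classifier_spec("tv_lrc", lambda1 = 0.05, lambda_tv = 0.05))
  for (sp in specs) {
    m1 <- train_classifier(pr$X, pr$y, sp, D = D)
    m2 <- train_classifier(pr$X[perm, ], pr$y[perm], sp, D = D)
    expect_equal(decision_scores(m1, probe), decision_scores(m2, probe),
                 tolerance = 1e-4)
  }
})
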