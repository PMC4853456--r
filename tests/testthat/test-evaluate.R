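test_that("ROC vertices and trapezoidal AUC match pair counting", {
  r <- roc_curve(c(0.9, 0.4, 0.5, 0.1), c(1, 1, -1, -1))
  expect_equal(r$auc, 0.75)  # 3 of 4 pairs concordant
  expect_equal(r$fpr[1], 0); expect_equal(r$tpr[1], 0)
  expect_equal(tail(r$fpr, 1), 1); expect_equal(tail(r$tpr, 1), 1)
  expect_true(!is.unsorted(r$fpr) && !is.unsorted(r$tpr))
  # perfect separation and all-ties
  expect_equal(roc_curve(c(3, 2, 1, 0), c(1, 1, -1, -1))$auc, 1)
  expect_equal(roc_curve(rep(1, 6), rep(c(1, -1), 3))$auc, 0.5)
  set.seed(17)
  for (i in 1:20) {
    n <- sample(6:30, 1)
    y <- rep(c(1, -1), length.out = n)[sample(n)]
    s <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # force ties
    expect_equal(roc_curve(s, y)$auc, pair_count_auc(s, y), tolerance = 1e-12)
  }
  expect_error(roc_curve(1:3, rep(1, 3)), "both classes")
})

test_that("LOOCV is perfect on a widely separated cohort and matches a
           fold-by-fold oracle", {
  skip_if_not_installed("e1071")
  # wide-margin synthetic cohort
  set.seed(18)
  X <- rbind(matrix(rnorm(8 * 4, 5), 8, 4), matrix(rnorm(8 * 4, -5), 8, 4))
  y <- rep(c(1, -1), each = 8)
  cv <- loocv(X, y, classifier_spec("svm", kernel = "linear"),
              list(fraction = 1, cost = 1))
  expect_equal(cv$accuracy, 1)
  # 6-subject toy: per-fold predictions match a brute-force enumeration with
  # an independent solver
  pr <- gaussian_problem(6, 3, seed = 19)
  grid <- list(fraction = 1, cost = 10)
  cv6 <- loocv(pr$X, pr$y, classifier_spec("svm", kernel = "linear",
                                           standardize = FALSE), grid)
  hand <- vapply(1:6, function(i) {
    fit <- e1071::svm(pr$X[-i, ], factor(pr$y[-i], levels = c(-1, 1)),
                      scale = FALSE, kernel = "linear", cost = 10)
    as.integer(as.character(predict(fit, pr$X[i, , drop = FALSE])))
  }, integer(1))
  expect_equal(cv6$folds$prediction, hand)
  # accuracy recomputes exactly from the stored per-fold table
  expect_equal(cv6$accuracy, mean(cv6$folds$prediction == cv6$folds$truth))
})

test_that("the fused C++ LOOCV path and the reference R path agree", {
  pr <- gaussian_problem(14, 25, seed = 20)
  grid <- list(fraction = c(0.2, 1), cost = c(0.5, 2), gamma = c(0.05, 0.2))
  sp <- classifier_spec("svm", kernel = "rbf")
  a <- loocv(pr$X, pr$y, sp, grid, engine = "auto")
  b <- loocv(pr$X, pr$y, sp, grid, engine = "r")
  expect_equal(a$accuracy, b$accuracy)
  expect_equal(a$folds$prediction, b$folds$prediction)
  expect_equal(a$chosen, b$chosen)
  expect_equal(a$folds$score, b$folds$score, tolerance = 1e-4)
})

test_that("a training fold that loses a class is a configuration error", {
  X <- matrix(rnorm(8), 4, 2)
  expect_error(loocv(X, c(1, -1, -1, -1), classifier_spec("svm"),
                     list(fraction = 1, cost = 1)),
               "configuration error")
})

test_that("null LOOCV accuracy sits at chance over replicate null datasets", {
  set.seed(21)
  accs <- vapply(1:60, function(i) {
    X <- matrix(rnorm(12 * 10), 12, 10)
    y <- rep(c(1, -1), each = 6)[sample(12)]
    loocv(X, y, classifier_spec("svm", kernel = "rbf"),
          list(fraction = c(0.5, 1), cost = 1, gamma = 0.1))$accuracy
  }, numeric(1))
  # grid-search optimism lifts the mean above exact chance; it must stay
  # inside a generous band around 0.5
  expect_gt(mean(accs), 0.35)
  expect_lt(mean(accs), 0.72)
})

test_that("permutation p-values follow the equal-or-superior counting rule", {
  pr <- gaussian_problem(12, 8, seed = 22)
  res <- permutation_test(pr$X, pr$y, classifier_spec("svm", kernel = "rbf"),
                          list(fraction = 1, cost = 1, gamma = 0.1),
                          n_perm = 40, seed = 5)
  expect_equal(res$p, mean(res$null_stats >= res$observed_stat))
  expect_equal(res$p_plus_one,
               (sum(res$null_stats >= res$observed_stat) + 1) / 41)
  expect_gte(res$p, 0); expect_lte(res$p, 1)
  # identical seed reproduces the null ensemble exactly
  res2 <- permutation_test(pr$X, pr$y, classifier_spec("svm", kernel = "rbf"),
                           list(fraction = 1, cost = 1, gamma = 0.1),
                           n_perm = 40, seed = 5)
  expect_identical(res$null_stats, res2$null_stats)
})

test_that("null ROC contours are pointwise quantiles, nested across levels", {
  # degenerate ensemble: every contour equals the common curve
  curve <- c(seq(0, 1, 0.25))
  ens <- matrix(rep(curve, 10), 10, byrow = TRUE)
  ct <- suppressWarnings(null_roc_contours(ens, levels = c(0.05, 0.2),
                                           fpr_grid = seq(0, 1, 0.25)))
  expect_equal(ct$p_0.05, curve)
  expect_equal(ct$p_0.2, curve)
  # three ordered step curves: the 0.34 contour is the middle curve
  e3 <- rbind(rep(0.2, 5), rep(0.5, 5), rep(0.8, 5))
  ct3 <- suppressWarnings(null_roc_contours(e3, levels = 0.34,
                                            fpr_grid = seq(0, 1, 0.25)))
  expect_equal(ct3$p_0.34, rep(0.5, 5))
  # nesting: smaller p -> higher contour
  set.seed(23)
  ens2 <- matrix(runif(200), 40, 5)
  ctn <- null_roc_contours(ens2, levels = c(0.05, 0.1, 0.3),
                           fpr_grid = seq(0, 1, 0.25))
  expect_true(all(ctn$p_0.05 >= ctn$p_0.1))
  expect_true(all(ctn$p_0.1 >= ctn$p_0.3))
})

test_that("nested-mode LOOCV runs and reports fold scores", {
  pr <- gaussian_problem(10, 6, seed = 24)
  cv <- loocv(pr$X, pr$y, classifier_spec("svm", kernel = "linear"),
              list(fraction = c(0.5, 1), cost = 1), nested = TRUE)
  expect_equal(nrow(cv$folds), 10)
  expect_true(isTRUE(cv$chosen$nested))
})
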