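test_that("the covariance map matches hand covariance and is antisymmetric", {
  X <- matrix(c(2, 2, 0, 0), ncol = 1)
  y <- c(1, 1, -1, -1)
  expect_equal(group_covariance_map(X, y), 4 / 3)
  # balanced mirrored values give exactly zero
  Xm <- matrix(c(1, -1, 1, -1), ncol = 1)
  expect_equal(group_covariance_map(Xm, y), 0)
  # label flip negates every voxel exactly
  set.seed(25)
  Xr <- matrix(rnorm(12 * 7), 12, 7)
  yr <- rep(c(1, -1), each = 6)
  expect_equal(group_covariance_map(Xr, -yr), -group_covariance_map(Xr, yr))
  expect_error(group_covariance_map(Xr, rep(1, 12)), "both classes")
})

test_that("TFCE reproduces the discrete-sum hand oracle on toy maps", {
  sk <- chain_skeleton(4, end_fraction = 0.25)
  out <- tfce(c(0, 2, 2, 0), sk, E = 0.5, H = 2, dh = 1)
  # middle cluster of size 2 at h = 1 and 2: sqrt(2) * (1 + 4) = 7.0711
  expect_equal(out, c(0, sqrt(2) * 5, sqrt(2) * 5, 0), tolerance = 1e-12)
  expect_equal(tfce(rep(0, 4), sk), rep(0, 4))
  # signed maps: negative lobe enhanced on the negated map and re-signed
  out2 <- tfce(c(-2, -2, 0, 2), sk, E = 0.5, H = 2, dh = 1)
  expect_lt(out2[1], 0); expect_gt(out2[4], 0)
  # brute-force cluster enumeration agrees on random maps and skeletons
  sk2 <- small_skeleton()
  set.seed(26)
  for (i in 1:5) {
    v <- rnorm(sk2$n_voxels)
    expect_equal(tfce(v, sk2, E = 0.5, H = 2, dh = 0.25),
                 brute_tfce(v, sk2$edges, 0.5, 2, 0.25), tolerance = 1e-10)
  }
})

test_that("TFCE integration converges as the step is refined", {
  sk <- chain_skeleton(30)
  v <- exp(-((1:30) - 15)^2 / 40)
  a <- tfce(v, sk, dh = 0.01)
  b <- tfce(v, sk, dh = 0.005)
  # Riemann-sum refinement: relative to the map-wide scale (voxels near the
  # suprathreshold boundary carry O(dh) absolute differences)
  expect_lt(max(abs(a - b)) / max(b), 0.01)
  expect_warning(tfce(v * 0.001, sk, dh = 1), "single integration step")
})

test_that("TFCE is monotone under pointwise map increases", {
  sk <- small_skeleton()
  set.seed(27)
  for (i in 1:20) {
    v <- pmax(rnorm(sk$n_voxels), 0)
    v2 <- v + runif(sk$n_voxels, 0, 0.5) * rbinom(sk$n_voxels, 1, 0.3)
    t1 <- tfce(v, sk, dh = 0.05)
    t2 <- tfce(v2, sk, dh = 0.05)
    expect_true(all(t2 >= t1 - 1e-10))
  }
})

test_that("max-statistic FWE p-values are valid and monotone in |TFCE|", {
  co <- strong_cohort()
  X <- assemble_feature_matrix(co, metric = "MD")
  res <- tfce_permutation_fwe(X, co$subjects$group, co$skeleton,
                              n_perm = 60, seed = 9)
  expect_true(all(res$p_fwe >= 1 / 60 & res$p_fwe <= 1))
  ord <- order(abs(res$tfce))
  expect_true(all(diff(res$p_fwe[ord]) <= 1e-12))
  # strong implanted effect: smallest FWE p in an end region
  idx <- which.min(res$p_fwe)
  expect_lte(res$p_fwe[idx], 0.05)
  # the most significant voxel lies where the implanted field is strong
  expect_gt(abs(effect_field(co$skeleton))[idx], 0.3)
})

test_that("bootstrap coefficient maps are deterministic with the identity
           hook equal to a full-data fit", {
  co <- strong_cohort()
  X <- assemble_feature_matrix(co, metric = "MD")
  y <- co$subjects$group
  sp <- classifier_spec("enet_lrc", lambda1 = 0.05, alpha = 0.5)
  ident <- bootstrap_coefficient_map(X, y, sp, n_boot = 1, seed = 1,
                                     resampler = function(n, b) seq_len(n))
  full <- coef(train_enet_lrc(X, y, sp))
  expect_equal(ident$mean_coef, full$coefficients, tolerance = 1e-10)
  b1 <- bootstrap_coefficient_map(X, y, sp, n_boot = 15, seed = 4)
  b2 <- bootstrap_coefficient_map(X, y, sp, n_boot = 15, seed = 4)
  expect_identical(b1$mean_coef, b2$mean_coef)
  # strong signal: non-zero mean coefficients align in sign with covariance
  covmap <- group_covariance_map(X, y)
  diag1 <- coef_covariance_diagnostics(b1$mean_coef, covmap)
  expect_gte(diag1$sign_agreement, 0.9)
})

test_that("coefficient-covariance diagnostics cover the identity and
           antisymmetric cases", {
  v <- c(0.5, -0.2, 0, 0.1, -0.4)
  d1 <- coef_covariance_diagnostics(v, v)
  expect_equal(d1$sign_agreement, 1); expect_equal(d1$r, 1)
  expect_equal(d1$n_nonzero, 4)
  d2 <- coef_covariance_diagnostics(v, -v)
  expect_equal(d2$sign_agreement, 0); expect_equal(d2$r, -1)
  # hand Pearson on a 5-voxel pair of maps over the support
  a <- c(1, 2, 0, -1, 3); b <- c(2, 1, 5, -2, 2)
  d3 <- coef_covariance_diagnostics(a, b)
  expect_equal(d3$r, cor(a[a != 0], b[a != 0]))
  d0 <- coef_covariance_diagnostics(rep(0, 5), b)
  expect_equal(d0$n_nonzero, 0L)
  expect_true(is.na(d0$r))
})
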