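test_that("every generated voxel satisfies the tensor-metric identities", {
  co <- strong_cohort()
  f <- co$features
  expect_equal(f$MD, (f$AD + 2 * f$RD) / 3, tolerance = 0)
  expect_true(all(f$FA >= 0 & f$FA <= 1))
  expect_true(all(f$AD > 0 & f$RD > 0))
  # lambda ordering: lambda2 = RD (1 + split) must not exceed lambda1 = AD
  split <- 0.3
  expect_true(all(f$AD >= f$RD * (1 + split)))
  expect_true(all(f$RD * (1 - split) > 0))
})

test_that("a stored seed regenerates the cohort bit for bit", {
  sk <- small_skeleton()
  a <- simulate_dti_cohort(sk, n_pos = 5, n_neg = 4, seed = 11)
  b <- simulate_dti_cohort(sk, n_pos = 5, n_neg = 4, seed = a$seed)
  expect_identical(a, b)
  c2 <- simulate_dti_cohort(sk, n_pos = 5, n_neg = 4, seed = 12)
  expect_false(identical(a$features$MD, c2$features$MD))
})

test_that("zero amplitude gives null group differences; the implanted
           amplitude is recovered at the frontal-end centre", {
  sk <- small_skeleton()
  null_co <- simulate_dti_cohort(sk, n_pos = 200, n_neg = 200,
                                 effect = list(metric = "MD", amplitude = 0),
                                 behaviour = NULL, seed = 3)
  X <- assemble_feature_matrix(null_co, metric = "MD")
  g <- null_co$subjects$group
  dmean <- colMeans(X[g == 1, ]) - colMeans(X[g == -1, ])
  se <- sqrt(apply(X[g == 1, ], 2, var) / 200 + apply(X[g == -1, ], 2, var) / 200)
  expect_true(all(abs(dmean) < 4 * se))

  amp <- 1e-4
  eff_co <- simulate_dti_cohort(sk, n_pos = 200, n_neg = 200,
                                effect = list(metric = "MD", amplitude = amp),
                                behaviour = NULL, seed = 4)
  Xe <- assemble_feature_matrix(eff_co, metric = "MD")
  w <- effect_field(sk)
  centre <- which.max(w)  # +1 by construction
  expect_equal(w[centre], 1)
  d <- mean(Xe[g == 1, centre]) - mean(Xe[g == -1, centre])
  se_c <- sqrt(var(Xe[g == 1, centre]) / 200 + var(Xe[g == -1, centre]) / 200)
  expect_lt(abs(d - amp), 2 * se_c)
})

test_that("amplitudes that break positivity are rejected", {
  expect_error(simulate_dti_cohort(small_skeleton(), n_pos = 3, n_neg = 3,
                                   effect = list(metric = "MD",
                                                 amplitude = 2e-3),
                                   behaviour = NULL, seed = 1),
               "invalid parameters")
  expect_error(simulate_dti_cohort(small_skeleton(), n_pos = 1, n_neg = 3),
               "at least 2")
})

test_that("behaviour scores reach the requested correlation with the tract
           summary", {
  sk <- chain_skeleton(20)
  co <- simulate_dti_cohort(sk, n_pos = 5000, n_neg = 5000,
                            effect = list(metric = "MD", amplitude = 0),
                            behaviour = NULL, seed = 5)
  co <- simulate_behaviour_scores(co, target_corr = c(aggression = -0.54),
                                  summary_metric = "AD", seed = 6)
  r <- cor(rowMeans(co$features$AD), co$subjects$aggression)
  expect_lt(abs(r - (-0.54)), 0.03)  # Fisher-z CI at n = 10,000
  # independence case
  co0 <- simulate_behaviour_scores(co, target_corr = c(mania = 0), seed = 7)
  r0 <- cor(rowMeans(co0$features$AD), co0$subjects$mania)
  expect_lt(abs(r0), 4 / sqrt(10000))
  expect_error(simulate_behaviour_scores(co, target_corr = c(mania = 1)),
               "below 1")
})

test_that("ROI time courses hit the target correlation", {
  tc <- simulate_roi_timecourses(10000, target_r = 0.7, seed = 8)
  expect_lt(abs(cor(tc$roi1, tc$roi2) - 0.7), 0.02)
  tc1 <- simulate_roi_timecourses(50, target_r = 1, seed = 9)
  expect_equal(cor(tc1$roi1, tc1$roi2), 1)
  expect_equal(nrow(simulate_roi_timecourses(seed = 1)), 150)
  expect_error(simulate_roi_timecourses(2), "at least 3")
})
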