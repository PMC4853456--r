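test_that("pooled t, Pearson and Fisher z reproduce hand values", {
  tt <- two_sample_ttest(c(1, 2, 3), c(3, 4, 5))
  # pooled variance 1, se = sqrt(2/3), t = -2/se = -sqrt(6)
  expect_equal(tt$t, -sqrt(6), tolerance = 1e-10)
  expect_equal(tt$df, 4)
  expect_equal(tt$p, 2 * pt(-sqrt(6), 4), tolerance = 1e-12)
  expect_equal(round(tt$p, 4), 0.0705)
  # symmetry and degenerate cases
  ts <- two_sample_ttest(c(3, 4, 5), c(1, 2, 3))
  expect_equal(ts$t, -tt$t); expect_equal(ts$p, tt$p)
  td <- two_sample_ttest(c(2, 2), c(2, 2))
  expect_equal(td$t, 0); expect_equal(td$p, 1)
  ti <- two_sample_ttest(c(3, 3), c(1, 1))
  expect_true(is.infinite(ti$t) && ti$t > 0); expect_equal(ti$p, 0)

  x <- c(1.2, -0.4, 2.5, 0.3, 1.8)
  yv <- c(0.7, 0.1, 3.0, -0.2, 2.1)
  pr <- pearson(x, yv)
  r_hand <- sum((x - mean(x)) * (yv - mean(yv))) /
    sqrt(sum((x - mean(x))^2) * sum((yv - mean(yv))^2))
  expect_equal(pr$r, r_hand, tolerance = 1e-10)
  t_hand <- r_hand * sqrt(3 / (1 - r_hand^2))
  expect_equal(pr$p, 2 * pt(-abs(t_hand), 3), tolerance = 1e-10)
  expect_equal(pearson(x, 2 * x + 1)$r, 1)
  expect_equal(pearson(x, -x)$r, -1)
  expect_error(pearson(x, rep(2, 5)), "degenerate")

  expect_equal(fisher_z(0), 0)
  expect_equal(round(fisher_z(0.5), 4), 0.5493)
  rs <- seq(-0.9, 0.9, 0.3)
  expect_equal(fisher_z(-rs), -fisher_z(rs))
  expect_warning(zi <- fisher_z(1), "infinite")
  expect_true(is.infinite(zi))
})

test_that("partial correlation: formula and residual routes agree to 1e-10", {
  set.seed(28)
  for (i in 1:20) {
    n <- 30
    z <- rnorm(n)
    x <- 0.5 * z + rnorm(n)
    yv <- -0.3 * z + rnorm(n)
    pc <- partial_correlation(x, yv, z)
    rx <- resid(lm(x ~ z)); ry <- resid(lm(yv ~ z))
    expect_equal(pc$r, cor(rx, ry), tolerance = 1e-10)
    expect_equal(pc$df, n - 3)
  }
  # covariate uncorrelated with both (population): partial approaches plain r
  set.seed(29)
  n <- 10000
  z <- rnorm(n); x <- rnorm(n); yv <- 0.5 * x + rnorm(n)
  expect_lt(abs(partial_correlation(x, yv, z)$r - cor(x, yv)), 0.02)
  expect_error(partial_correlation(x[1:20], z[1:20], z[1:20]), "collinear")
})

test_that("ROI connectivity returns Pearson r with its Fisher z", {
  tc <- simulate_roi_timecourses(10000, target_r = 0.7, seed = 30)
  res <- roi_connectivity(tc$roi1, tc$roi2)
  expect_lt(abs(res$r - 0.7), 0.02)
  expect_equal(res$fisher_z, atanh(res$r))
  # identical standardized series: r = 1, infinite z flagged
  s <- as.vector(scale(rnorm(50)))
  expect_warning(res1 <- roi_connectivity(s, s), "degenerate|infinite")
  expect_equal(res1$r, 1)
  expect_true(is.infinite(res1$fisher_z))
  # anti-phase sine pair: r = -1 up to rounding, Fisher z diverges
  tt <- seq(0, 4 * pi, length.out = 200)
  resa <- suppressWarnings(roi_connectivity(sin(tt), -sin(tt)))
  expect_equal(resa$r, -1, tolerance = 1e-12)
  expect_lt(resa$fisher_z, -15)
  expect_error(roi_connectivity(1:5, 1:6), "alignment")
})

test_that("group comparisons on default cohorts go in the implanted
           directions with p < 0.05", {
  # five replicate cohorts at the default effect sizes: directions must be
  # right every time; significance in a clear majority (single-cohort power
  # for the weakest score effect is around 90% at n = 19 vs 17)
  sk <- make_skeleton(60, seed = 2)
  tabs <- lapply(31:35, function(s)
    behaviour_stats_table(simulate_dti_cohort(sk, seed = s)))
  sig <- sapply(tabs, function(tab) {
    grp <- tab[tab$test == "two_sample_t", ]
    rt <- grp[grp$variables == "rt_mean", ]
    expect_lt(rt$statistic, 0)  # athletes faster
    ok <- c(rt_mean = rt$p < 0.05)
    for (v in c("errors", "aggression", "mania")) {
      row <- grp[grp$variables == v, ]
      expect_gt(row$statistic, 0)  # athletes higher
      ok[v] <- row$p < 0.05
    }
    ok
  })
  expect_true(all(rowSums(sig) >= 3))
  # correlation battery is present with BH column filled
  tab1 <- tabs[[1]]
  expect_true(all(!is.na(tab1$p_bh[tab1$test != "two_sample_t"])))
})
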