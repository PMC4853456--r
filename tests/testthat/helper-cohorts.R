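# Shared fixtures built in code: small skeletons and cohorts reused across
# test files. Sizes are kept small so the whole suite stays fast; the
# acceptance tests build their own full-size inputs.

chain_skeleton <- function(n, end_fraction = 0.2) {
  skeleton_from_coords(cbind(0:(n - 1), 0L, 0L), end_fraction = end_fraction)
}

small_skeleton <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_skeleton(60, seed = 42)
    cache
  }
})

# cohort with a strong implanted MD effect, behaviour on
strong_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_dti_cohort(small_skeleton(), n_pos = 12, n_neg = 10,
                                    effect = list(metric = "MD",
                                                  amplitude = 3e-4,
                                                  taper = 0.15),
                                    seed = 7)
    cache
  }
})

# label-exchangeable cohort (no implanted effect, no behaviour)
null_cohort <- function(seed = 1, n_pos = 8, n_neg = 8) {
  simulate_dti_cohort(small_skeleton(), n_pos = n_pos, n_neg = n_neg,
                      effect = list(metric = "MD", amplitude = 0),
                      behaviour = NULL, seed = seed)
}

# plain Gaussian feature matrix with balanced labels
gaussian_problem <- function(n = 16, p = 20, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  y <- rep(c(1, -1), length.out = n)[sample(n)]
  list(X = X, y = y)
}

skeleton_dims_for_test <- function(sk) tractmvpa:::skeleton_dims(sk)
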