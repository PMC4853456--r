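# Synthetic DTI cohort generator.
#
# Generation starts at derived tensor metrics (no raw diffusion signal or
# tractography is simulated). Per voxel the eigenvalue triple is built as
#   lambda1 = AD,  lambda2 = RD * (1 + split),  lambda3 = RD * (1 - split)
# so that RD = (lambda2 + lambda3)/2 and MD = (AD + 2 RD)/3 hold exactly, and
# FA follows from the standard tensor formula
#   FA = sqrt(3/2) * sqrt(sum((lambda - mean)^2)) / sqrt(sum(lambda^2)).
# (The FA formula is conventional; it is stated here because the generator is
# defined in terms of it.)

#' Spatial group-effect field along a skeleton
#'
#' Returns one weight per voxel: +1 at the frontal-end centre, -1 at the
#' temporal-end centre, tapering smoothly (Gaussian in arc position) to about
#' zero mid-tract. Multiplied by the effect amplitude this is the implanted
#' expected group difference pattern, positive frontally and negative
#' temporally.
#'
#' @param skeleton a `tract_skeleton`.
#' @param taper Gaussian taper width in arc units (tract length = 1).
#' @return numeric vector of length `n_voxels`, equal to +1 at the
#'   frontal-centre voxel.
#' @export
effect_field <- function(skeleton, taper = 0.15) {
  arc <- skeleton$arc
  tf <- mean(arc[skeleton$end_labels == "frontal"])
  tt <- mean(arc[skeleton$end_labels == "temporal"])
  w <- exp(-((arc - tf) / taper)^2) - exp(-((arc - tt) / taper)^2)
  centre <- which.min(abs(arc - tf))
  w / w[centre]
}

# Graph-smoothing matrix: exponential kernel in graph distance, rows scaled to
# unit L2 norm so that smoothing an iid N(0,1) field preserves unit variance
# per voxel while introducing spatial correlation.
smoothing_matrix <- function(skeleton, decay = 5) {
  d <- igraph::distances(skeleton_graph(skeleton))
  K <- exp(-d / decay)
  K / sqrt(rowSums(K^2))
}

#' Simulate a DTI cohort with an implanted end-localized group effect
#'
#' Generates per-subject voxelwise FA/MD/AD/RD maps on a skeleton. Each
#' subject's diffusivities are baseline values plus a global subject offset,
#' a spatially smooth noise field (exponential kernel on the skeleton graph),
#' and a group effect of the chosen amplitude following [effect_field()]:
#' higher MD in the +1 group at the frontal end, lower at the temporal end.
#' Behavioural outcomes (SART reaction time and commission errors,
#' aggression and mania scores) are drawn with group-dependent parameters so
#' that the +1 "athlete" group is faster, makes more errors, and scores
#' higher on aggression and mania.
#'
#' @param skeleton a `tract_skeleton`.
#' @param n_pos,n_neg subjects in the +1 (athlete) and -1 (control) groups;
#'   defaults 19 and 17, mirroring the study cohort.
#' @param effect list: `metric` (`"MD"`, `"AD"` or `"RD"`; which diffusivity
#'   carries the implanted difference), `amplitude` (expected group difference
#'   in that metric at the frontal-end centre, mm^2/s), `taper` (arc units).
#'   With `metric = "MD"` the shift is applied equally to AD and RD so the MD
#'   difference equals the amplitude exactly.
#' @param noise list: `sd_subject` (global per-subject offset SD, mm^2/s),
#'   `sd_voxel` (spatial field SD per voxel, mm^2/s), `decay` (smoothing
#'   kernel decay length, voxels). Noise fields are truncated at +/- 5 SD so
#'   diffusivities stay positive at sane amplitudes.
#' @param baseline list of healthy white-matter baseline diffusivities
#'   (mm^2/s) and the lambda2/lambda3 `split`; conventional skeleton
#'   magnitudes, AD 1.2e-3 and RD 0.55e-3 (hence MD about 0.77e-3).
#' @param behaviour list of group-specific behavioural parameters; see
#'   Details in the package vignette. Set to `NULL` to skip behaviour.
#' @param seed integer; one global seed fans out to per-subject streams, so
#'   the cohort (and each subject) is bit-for-bit reproducible.
#' @return An object of class `dti_cohort`: list with `skeleton`, `subjects`
#'   (data frame: id, group, age, rt_mean, errors, aggression, mania),
#'   `features` (named list of subject x voxel matrices for FA/MD/AD/RD),
#'   `effect_spec`, and `seed`.
#' @export
simulate_dti_cohort <- function(skeleton, n_pos = 19, n_neg = 17,
                                effect = list(metric = "MD", amplitude = 6e-5,
                                              taper = 0.15),
                                noise = list(sd_subject = 2e-5, sd_voxel = 2e-5,
                                             decay = 5),
                                baseline = list(AD = 1.2e-3, RD = 0.55e-3,
                                                split = 0.3),
                                behaviour = default_behaviour_model(),
                                seed = 1) {
  stopifnot(inherits(skeleton, "tract_skeleton"))
  if (n_pos < 2 || n_neg < 2) stop("at least 2 subjects per group are required")
  amplitude <- effect$amplitude %||% 6e-5
  metric <- match.arg(effect$metric %||% "MD", c("MD", "AD", "RD"))
  taper <- effect$taper %||% 0.15
  sd_subject <- noise$sd_subject %||% 2e-5
  sd_voxel <- noise$sd_voxel %||% 2e-5
  decay <- noise$decay %||% 5
  if (!is.finite(amplitude)) stop("effect amplitude must be finite")
  if (sd_subject <= 0 || sd_voxel <= 0) stop("noise variances must be positive")

  n <- n_pos + n_neg
  V <- skeleton$n_voxels
  group <- c(rep(1, n_pos), rep(-1, n_neg))
  w <- effect_field(skeleton, taper)
  S <- smoothing_matrix(skeleton, decay)

  z_ad <- matrix(0, V, n)
  z_rd <- matrix(0, V, n)
  subj_off <- numeric(n)
  age <- numeric(n)
  for (i in seq_len(n)) {
    draws <- with_seed(child_seed(seed, i), {
      list(z1 = rnorm(V), z2 = rnorm(V), off = rnorm(1), age = rnorm(1, 45, 6))
    })
    z_ad[, i] <- draws$z1
    z_rd[, i] <- draws$z2
    subj_off[i] <- draws$off
    age[i] <- draws$age
  }
  clamp5 <- function(m) pmin(pmax(m, -5), 5)
  field_ad <- clamp5(S %*% z_ad) * sd_voxel
  field_rd <- clamp5(S %*% z_rd) * sd_voxel
  off <- pmin(pmax(subj_off, -5), 5) * sd_subject

  # group shift per voxel x subject; half-amplitude per group so the
  # between-group difference equals the amplitude
  shift <- outer(w, group) * (amplitude / 2)
  AD <- matrix(baseline$AD, V, n) + rep(off, each = V) + field_ad
  RD <- matrix(baseline$RD, V, n) + rep(off, each = V) + field_rd
  if (metric == "MD") {
    AD <- AD + shift; RD <- RD + shift
  } else if (metric == "AD") {
    AD <- AD + shift
  } else {
    RD <- RD + shift
  }

  split <- baseline$split %||% 0.3
  l2 <- RD * (1 + split)
  l3 <- RD * (1 - split)
  if (any(l3 <= 0) || any(AD < l2))
    stop("invalid parameters: effect amplitude and noise produce eigenvalues ",
         "violating lambda1 >= lambda2 >= lambda3 > 0", call. = FALSE)
  MD <- (AD + 2 * RD) / 3
  lbar <- MD
  FA <- sqrt(3 / 2) * sqrt((AD - lbar)^2 + (l2 - lbar)^2 + (l3 - lbar)^2) /
    sqrt(AD^2 + l2^2 + l3^2)

  ids <- sprintf("S%03d", seq_len(n))
  subjects <- data.frame(id = ids, group = group, age = round(age, 1),
                         rt_mean = NA_real_, errors = NA_integer_,
                         aggression = NA_real_, mania = NA_real_,
                         stringsAsFactors = FALSE)
  if (!is.null(behaviour)) {
    sch <- make_sart_schedule(seed = child_seed(seed, 10001L))
    for (i in seq_len(n)) {
      par <- if (group[i] > 0) behaviour$athlete else behaviour$control
      out <- simulate_sart(sch, par, seed = child_seed(seed, 20000L + i))
      qs <- with_seed(child_seed(seed, 30000L + i), {
        c(rnorm(1, par$aggression_mean, par$score_sd),
          rnorm(1, par$mania_mean, par$score_sd))
      })
      subjects$rt_mean[i] <- out$rt_mean
      subjects$errors[i] <- out$errors
      subjects$aggression[i] <- qs[1]
      subjects$mania[i] <- qs[2]
    }
  }

  features <- lapply(list(FA = FA, MD = MD, AD = AD, RD = RD), function(m) {
    m <- t(m)
    dimnames(m) <- list(ids, NULL)
    m
  })
  structure(list(skeleton = skeleton, subjects = subjects, features = features,
                 effect_spec = list(metric = metric, amplitude = amplitude,
                                    taper = taper, field = w,
                                    noise = list(sd_subject = sd_subject,
                                                 sd_voxel = sd_voxel,
                                                 decay = decay),
                                    behaviour = behaviour),
                 seed = seed),
            class = "dti_cohort")
}

#' Default group-specific behavioural parameters
#'
#' The +1 (athlete) group responds faster, commits more no-go errors, and
#' scores about one questionnaire SD higher on aggression and mania; effect
#' sizes are chosen to mirror the qualitative group separation of the study's
#' behavioural findings at n of about 19 vs 17.
#' @return nested list of per-group response-model parameters.
#' @export
default_behaviour_model <- function() {
  list(athlete = list(rt_mean = 295, rt_sd = 35, p_commission = 0.40,
                      p_omission = 0.02, aggression_mean = 58, mania_mean = 55,
                      score_sd = 8),
       control = list(rt_mean = 340, rt_sd = 35, p_commission = 0.16,
                      p_omission = 0.02, aggression_mean = 47, mania_mean = 46,
                      score_sd = 8))
}

#' Regenerate behavioural scores with a target correlation to a tract summary
#'
#' Overwrites the named scores with draws from a linear-Gaussian model whose
#' population correlation with a per-subject tract summary (the row mean of
#' one DTI metric) equals `target_corr`, emulating the reported negative
#' AD-behaviour correlations. Error counts are rounded and clamped to the
#' valid 0-25 range afterwards, which perturbs their realized correlation
#' slightly; continuous scores are exact in population.
#'
#' @param cohort a `dti_cohort`.
#' @param target_corr named numeric vector, names among
#'   `rt_mean`, `errors`, `aggression`, `mania`; values in (-1, 1).
#' @param summary_metric DTI metric whose per-subject mean is the correlate.
#' @param scales named list of `c(mean, sd)` pairs for the output scale of
#'   each score.
#' @param seed integer seed.
#' @return the cohort with the named subject columns replaced.
#' @export
simulate_behaviour_scores <- function(cohort,
                                      target_corr = c(aggression = -0.54),
                                      summary_metric = "AD",
                                      scales = list(rt_mean = c(320, 40),
                                                    errors = c(7, 3),
                                                    aggression = c(52, 9),
                                                    mania = c(50, 9)),
                                      seed = 1) {
  stopifnot(inherits(cohort, "dti_cohort"))
  if (any(abs(target_corr) >= 1))
    stop("target correlations must have absolute value below 1")
  bad <- setdiff(names(target_corr), names(scales))
  if (length(bad)) stop("unknown score name(s): ", paste(bad, collapse = ", "))
  x <- rowMeans(cohort$features[[summary_metric]])
  if (sd(x) == 0)
    stop("degenerate input: tract summary is constant across subjects")
  xs <- as.vector(scale(x))
  n <- length(xs)
  for (j in seq_along(target_corr)) {
    nm <- names(target_corr)[j]
    r <- target_corr[[j]]
    z <- with_seed(child_seed(seed, j), rnorm(n))
    latent <- r * xs + sqrt(1 - r^2) * z
    val <- scales[[nm]][1] + scales[[nm]][2] * latent
    if (nm == "errors") val <- pmin(pmax(round(val), 0), 25)
    cohort$subjects[[nm]] <- val
  }
  cohort
}

#' Simulate a pair of ROI time courses with a target correlation
#'
#' Bivariate Gaussian series with population correlation `target_r`. The
#' default length of 150 volumes reflects a 5-minute resting-state run at a
#' 2-s TR with the first four volumes discarded.
#'
#' @param n_timepoints number of volumes (>= 3).
#' @param tr repetition time in seconds.
#' @param target_r population correlation in `[-1, 1]`.
#' @param seed integer seed.
#' @return data frame with columns `time`, `roi1`, `roi2`; attribute `tr`.
#' @export
simulate_roi_timecourses <- function(n_timepoints = 150, tr = 2,
                                     target_r = 0.7, seed = 1) {
  if (n_timepoints < 3) stop("n_timepoints must be at least 3")
  if (abs(target_r) > 1) stop("target_r must lie in [-1, 1]")
  dat <- with_seed(seed, {
    z1 <- rnorm(n_timepoints)
    z2 <- if (abs(target_r) == 1) sign(target_r) * z1
          else target_r * z1 + sqrt(1 - target_r^2) * rnorm(n_timepoints)
    data.frame(time = (seq_len(n_timepoints) - 1) * tr, roi1 = z1, roi2 = z2)
  })
  attr(dat, "tr") <- tr
  dat
}

#' @export
print.dti_cohort <- function(x, ...) {
  cat(sprintf("dti_cohort: %d subjects (%d +1 / %d -1), %d voxels, seed %d\n",
              nrow(x$subjects), sum(x$subjects$group == 1),
              sum(x$subjects$group == -1), x$skeleton$n_voxels, x$seed))
  cat(sprintf("  implanted effect: %s amplitude %.2e mm^2/s\n",
              x$effect_spec$metric, x$effect_spec$amplitude))
  invisible(x)
}
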