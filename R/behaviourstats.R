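# Univariate statistical layer: two-sample t tests, Pearson and
# age-partialled correlations, the Fisher z transform, and ROI-pair
# functional connectivity.

#' Two-sample pooled-variance t test (two-tailed)
#'
#' Student's t with pooled variance and df = n1 + n2 - 2 (the plain
#' two-sample t test; Welch available via `var_equal = FALSE`). Degenerate
#' zero-variance input returns t = 0, p = 1 when the means agree and an
#' infinite-t sentinel with p = 0 otherwise.
#'
#' @param a,b numeric samples (each of size >= 2).
#' @param var_equal pooled variance (default) or Welch.
#' @return list with `t`, `df`, `p`, `mean_a`, `mean_b`.
#' @export
two_sample_ttest <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2 || length(b) < 2) stop("each sample needs at least 2 values")
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1,
                  mean_a = mean(a), mean_b = mean(b)))
    return(list(t = sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2, p = 0,
                mean_a = mean(a), mean_b = mean(b)))
  }
  ht <- t.test(a, b, var.equal = var_equal)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_a = mean(a), mean_b = mean(b))
}

#' Pearson correlation with two-tailed p-value
#'
#' Standard product-moment r; p from `t = r sqrt((n-2)/(1-r^2))` with
#' df = n - 2.
#'
#' @param x,y numeric vectors (n >= 3, both non-constant).
#' @return object of class `correlation_result`: `r`, `p`, `n`, `df`,
#'   `controlled` (empty).
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("alignment error: unequal lengths")
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0)
    stop("degenerate input: constant vector has no correlation")
  ht <- cor.test(x, y, method = "pearson")
  structure(list(r = unname(ht$estimate), p = ht$p.value, n = n, df = n - 2,
                 controlled = character(0)),
            class = "correlation_result")
}

#' Partial correlation controlling for one covariate
#'
#' First-order partial correlation
#' \deqn{r_{xy.z} = \frac{r_{xy} - r_{xz} r_{yz}}
#'                       {\sqrt{(1 - r_{xz}^2)(1 - r_{yz}^2)}}}
#' which equals the correlation of the residuals from simple linear
#' regressions of x and y on z. Two-tailed p from df = n - 3.
#'
#' @param x,y numeric vectors; @param z the covariate (e.g. age).
#' @return a `correlation_result` with `controlled = "z"`.
#' @export
partial_correlation <- function(x, y, z) {
  n <- length(x)
  if (length(y) != n || length(z) != n) stop("alignment error: unequal lengths")
  if (n < 4) stop("need at least 4 observations")
  if (sd(x) == 0 || sd(y) == 0 || sd(z) == 0)
    stop("degenerate input: constant vector")
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  if (abs(rxz) >= 1 - 1e-12 || abs(ryz) >= 1 - 1e-12)
    stop("degenerate input: covariate is collinear with x or y")
  r <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  df <- n - 3
  tstat <- r * sqrt(df / (1 - r^2))
  structure(list(r = r, p = 2 * pt(-abs(tstat), df), n = n, df = df,
                 controlled = "z"),
            class = "correlation_result")
}

#' Fisher z transform of a correlation coefficient
#'
#' `z = arctanh(r)`, variance-stabilizing and odd in r. |r| = 1 returns an
#' infinite sentinel with a warning.
#'
#' @param r correlation value(s) in `[-1, 1]`.
#' @return z value(s).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1)) stop("|r| cannot exceed 1")
  if (any(abs(r) == 1))
    warning("|r| = 1 transforms to an infinite Fisher z")
  atanh(r)
}

#' ROI-pair functional connectivity
#'
#' Pearson correlation between two time courses plus its Fisher z value.
#'
#' @param tc1,tc2 numeric time courses of equal length (>= 3, non-constant).
#' @return a `correlation_result` with an extra `fisher_z` element.
#' @export
roi_connectivity <- function(tc1, tc2) {
  if (length(tc1) != length(tc2)) stop("alignment error: unequal lengths")
  res <- pearson(tc1, tc2)
  res$fisher_z <- if (abs(res$r) >= 1) {
    warning("|r| = 1: infinite Fisher z (degenerate connectivity)")
    sign(res$r) * Inf
  } else fisher_z(res$r)
  res
}

#' Behavioural and tract-correlate statistics table for a cohort
#'
#' Group comparisons (two-tailed pooled t) of reaction time, errors,
#' aggression and mania, plus Pearson and age-partialled correlations of the
#' per-subject tract summaries (mean of each DTI metric) with each
#' behavioural score within the +1 group, in tidy one-row-per-test form.
#' Benjamini-Hochberg adjusted p-values are reported alongside for the
#' exploratory correlation battery (the primary inference stays at
#' uncorrected p < 0.05, two-tailed, matching the exploratory design).
#'
#' @param cohort a `dti_cohort`.
#' @return data frame: one row per test with `test`, `variables`, `group`,
#'   `n`, `statistic`, `df`, `r`, `p`, `p_bh`, `covariates`.
#' @export
behaviour_stats_table <- function(cohort) {
  stopifnot(inherits(cohort, "dti_cohort"))
  sub <- cohort$subjects
  g <- sub$group
  rows <- list()
  for (v in c("rt_mean", "errors", "aggression", "mania")) {
    tt <- two_sample_ttest(sub[[v]][g == 1], sub[[v]][g == -1])
    rows[[length(rows) + 1]] <- data.frame(
      test = "two_sample_t", variables = v, group = "athlete_vs_control",
      n = nrow(sub), statistic = tt$t, df = tt$df, r = NA_real_, p = tt$p,
      covariates = "")
  }
  ath <- which(g == 1)
  for (metric in names(cohort$features)) {
    summ <- rowMeans(cohort$features[[metric]])[ath]
    for (v in c("rt_mean", "errors", "aggression", "mania")) {
      sc <- sub[[v]][ath]
      pr <- pearson(summ, sc)
      pc <- partial_correlation(summ, sc, sub$age[ath])
      rows[[length(rows) + 1]] <- data.frame(
        test = "pearson", variables = paste0("mean_", metric, "~", v),
        group = "athlete", n = pr$n, statistic = NA_real_, df = pr$df,
        r = pr$r, p = pr$p, covariates = "")
      rows[[length(rows) + 1]] <- data.frame(
        test = "partial_pearson", variables = paste0("mean_", metric, "~", v),
        group = "athlete", n = pc$n, statistic = NA_real_, df = pc$df,
        r = pc$r, p = pc$p, covariates = "age")
    }
  }
  out <- do.call(rbind, rows)
  corr_rows <- out$test != "two_sample_t"
  out$p_bh <- NA_real_
  out$p_bh[corr_rows] <- stats::p.adjust(out$p[corr_rows], method = "BH")
  out
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("r = %.3f, p = %.4g (n = %d, df = %d%s)\n", x$r, x$p, x$n, x$df,
              if (length(x$controlled) && nzchar(x$controlled[1]))
                paste0(", controlling ", paste(x$controlled, collapse = ", "))
              else ""))
  invisible(x)
}
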