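#' Group summary statistics
#'
#' The comparison battery accepts either raw per-subject vectors or `(n,
#' mean, sd)` summaries — the latter lets printed cohort tables be re-analyzed
#' directly. Both entry points agree exactly when the summary is computed
#' from the vector.
#'
#' @param n group size (>= 2).
#' @param mean group mean.
#' @param sd group standard deviation (n-1 denominator), >= 0.
#' @return an object of class `group_summary`.
#' @export
group_summary <- function(n, mean, sd) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop_nccthist("group size must be >= 2")
  assert_number(mean, "mean"); assert_number(sd, "sd")
  if (sd < 0) stop_nccthist("'sd' must be >= 0")
  structure(list(n = n, mean = mean, sd = sd), class = "group_summary")
}

as_group_summary <- function(x) {
  if (inherits(x, "group_summary")) return(x)
  x <- as.numeric(x)
  if (length(x) < 2L) stop_nccthist("group vectors need length >= 2")
  group_summary(length(x), mean(x), stats::sd(x))
}

#' Two-sample pooled-variance (Student) t-test
#'
#' Pooled rather than Welch: applied to the published cohort summary rows the
#' pooled statistic reproduces the printed t-values, so it is the study's
#' estimator. `df = n_a + n_b - 2`; two-sided p. If both groups have zero
#' variance, equal means give `t = 0, p = 1` and unequal means are an error
#' (the statistic is undefined).
#'
#' @param a,b numeric vectors or [group_summary()] objects.
#' @return list with `t`, `df`, `p`, `mean_difference`, `pooled_sd`.
#' @export
pooled_t <- function(a, b) {
  a <- as_group_summary(a); b <- as_group_summary(b)
  df <- a$n + b$n - 2L
  sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
  diff <- a$mean - b$mean
  if (sp2 <= 0) {
    if (diff == 0) return(list(t = 0, df = df, p = 1, mean_difference = 0, pooled_sd = 0))
    stop_nccthist("degenerate: zero pooled variance with unequal means")
  }
  se <- sqrt(sp2) * sqrt(1 / a$n + 1 / b$n)
  t <- diff / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
       mean_difference = diff, pooled_sd = sqrt(sp2))
}

#' One-way analysis of variance
#'
#' Standard between/within sum-of-squares decomposition, accepting raw
#' vectors or `(n, mean, sd)` summaries (between-SS from the means, within-SS
#' from the sds). For two groups, `F = t^2` of [pooled_t()] exactly.
#'
#' @param groups list of numeric vectors and/or [group_summary()] objects.
#' @return list with `F`, `df1`, `df2`, `p`.
#' @export
oneway_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop_nccthist("need at least 2 groups")
  gs <- lapply(groups, as_group_summary)
  n <- vapply(gs, `[[`, integer(1), "n")
  m <- vapply(gs, `[[`, numeric(1), "mean")
  s <- vapply(gs, `[[`, numeric(1), "sd")
  N <- sum(n); k <- length(gs)
  grand <- sum(n * m) / N
  ssb <- sum(n * (m - grand)^2)
  ssw <- sum((n - 1) * s^2)
  df1 <- k - 1L; df2 <- N - k
  if (ssw <= 0) {
    if (ssb == 0) return(list(F = 0, df1 = df1, df2 = df2, p = 1))
    stop_nccthist("degenerate: zero within-group variance with unequal means")
  }
  F <- (ssb / df1) / (ssw / df2)
  list(F = F, df1 = df1, df2 = df2, p = stats::pf(F, df1, df2, lower.tail = FALSE))
}

#' Cohen's d (pooled-SD standardized mean difference)
#'
#' \eqn{d = (\bar x_a - \bar x_b) / s_p} with the n-1-weighted pooled SD.
#'
#' @param a,b numeric vectors or [group_summary()] objects.
#' @return effect size d.
#' @export
cohens_d <- function(a, b) {
  a <- as_group_summary(a); b <- as_group_summary(b)
  sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2)
  if (sp2 <= 0) {
    if (a$mean == b$mean) return(0)
    stop_nccthist("degenerate: zero pooled SD")
  }
  (a$mean - b$mean) / sqrt(sp2)
}

#' Bonferroni correction
#'
#' `p' = min(1, m p)`. The default family size is 4 — the four histogram
#' metrics tested at a fixed group contrast.
#'
#' @param p_values numeric vector of raw p-values in `[0, 1]`.
#' @param m family size, `m >= length(p_values)`.
#' @return adjusted p-values.
#' @export
bonferroni <- function(p_values, m = 4L) {
  p_values <- as.numeric(p_values)
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop_nccthist("p-values must lie in [0, 1]")
  if (m < length(p_values)) stop_nccthist("'m' must be >= length(p_values)")
  pmin(1, m * p_values)
}

#' Percentile bootstrap CI for a two-sample statistic
#'
#' Resamples each group with replacement `n_boot` times and returns the
#' percentile interval of the statistic (default: difference of means). The
#' seed is mandatory so every interval is reproducible.
#'
#' @param x,y numeric vectors (the two groups).
#' @param statistic function of `(x, y)`; default `mean(x) - mean(y)`.
#' @param n_boot number of bootstrap replicates (>= 100; default 2000).
#' @param seed integer RNG seed (required).
#' @param conf confidence level, default 0.95.
#' @return list with `low`, `high`, `replicates` (the bootstrap draws).
#' @export
bootstrap_ci <- function(x, y, statistic = NULL, n_boot = 2000L, seed,
                         conf = 0.95) {
  if (missing(seed)) stop_nccthist("'seed' is required for reproducibility")
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1L || length(y) < 1L) stop_nccthist("empty input")
  n_boot <- as.integer(n_boot)
  if (n_boot < 100L) stop_nccthist("'n_boot' must be >= 100")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  if (is.null(statistic)) {
    # fast path for the default mean-difference statistic
    bx <- matrix(x[sample.int(length(x), length(x) * n_boot, replace = TRUE)], n_boot)
    by <- matrix(y[sample.int(length(y), length(y) * n_boot, replace = TRUE)], n_boot)
    reps <- rowMeans(bx) - rowMeans(by)
  } else {
    reps <- vapply(seq_len(n_boot), function(i) {
      statistic(x[sample.int(length(x), replace = TRUE)],
                y[sample.int(length(y), replace = TRUE)])
    }, numeric(1))
  }
  alpha <- (1 - conf) / 2
  qs <- stats::quantile(reps, c(alpha, 1 - alpha), names = FALSE, type = 7)
  list(low = qs[1], high = qs[2], replicates = reps)
}

#' One-way repeated-measures ANOVA (time effect, subjects as blocks)
#'
#' Tests metric evolution over the anchor time grid with subjects as their
#' own controls. Sphericity is assumed (no Greenhouse–Geisser correction).
#' Input is either a complete subjects-by-times numeric matrix, or a list of
#' trajectories plus a metric name, in which case each subject's scans are
#' matched to the anchor grid by nearest time within `tol` minutes; subjects
#' missing an anchor make the design unbalanced and are reported in the
#' error. With two time points, `F` equals the squared paired t statistic.
#'
#' @param x subjects-by-times matrix, or a list of trajectories
#'   (see [as_trajectories()]).
#' @param metric metric column (e.g. `"entropy_bits"`), for trajectory input.
#' @param anchors anchor times in minutes; default the standard scan grid.
#' @param tol nearest-scan matching tolerance in minutes (default 15).
#' @return list with `F`, `df1`, `df2`, `p`.
#' @export
rm_anova <- function(x, metric = "entropy_bits",
                     anchors = c(0, 60, 81.5, 94, 120, 180), tol = 15) {
  if (!is.matrix(x)) {
    mat <- anchor_matrix(x, metric, anchors, tol)
    bad <- rownames(mat)[apply(mat, 1L, function(r) any(is.na(r)))]
    if (length(bad))
      stop_nccthist("unbalanced repeated-measures design; subjects missing anchors: ",
                    paste(bad, collapse = ", "))
    x <- mat
  }
  if (any(is.na(x))) stop_nccthist("repeated-measures matrix contains NA")
  if (ncol(x) < 2L) stop_nccthist("need >= 2 time points")
  if (nrow(x) < 2L) stop_nccthist("need >= 2 subjects")
  d <- data.frame(y = as.vector(x),
                  time = factor(rep(seq_len(ncol(x)), each = nrow(x))),
                  subject = factor(rep(seq_len(nrow(x)), times = ncol(x))))
  fit <- stats::aov(y ~ time + Error(subject), data = d)
  tab <- summary(fit)[["Error: Within"]][[1L]]
  list(F = tab["time", "F value"], df1 = tab["time", "Df"],
       df2 = tab["Residuals", "Df"], p = tab["time", "Pr(>F)"])
}

#' Cohort comparison table (one row per histogram metric)
#'
#' For each metric, compares cortical vs BG lesion values at a time anchor
#' (default baseline): group means and SDs, mean difference, one-way ANOVA F
#' and p, pooled t and raw/Bonferroni-adjusted p, Cohen's d, and a percentile
#' bootstrap CI of the mean difference.
#'
#' @param metrics long-format metrics data.frame (see [metric_row()]).
#' @param at_time time anchor in minutes (default 0 = baseline).
#' @param tol nearest-scan tolerance in minutes.
#' @param metric_cols metrics to compare.
#' @param m Bonferroni family size (default: number of metrics).
#' @param n_boot,seed bootstrap settings (see [bootstrap_ci()]).
#' @param alpha significance level applied to adjusted p-values.
#' @return data.frame with one row per metric.
#' @export
compare_cohort <- function(metrics, at_time = 0, tol = 15,
                           metric_cols = c("sd", "skewness", "kurtosis_excess",
                                           "entropy_bits"),
                           m = length(metric_cols), n_boot = 2000L, seed = 1L,
                           alpha = 0.05) {
  les <- metrics[metrics$role == "lesion", , drop = FALSE]
  # nearest scan to the anchor, per subject
  pick <- do.call(rbind, lapply(split(les, les$case_id), function(d) {
    i <- which.min(abs(d$time_min - at_time))
    if (abs(d$time_min[i] - at_time) > tol) return(NULL)
    d[i, , drop = FALSE]
  }))
  if (is.null(pick) || !nrow(pick)) stop_nccthist("no scans near the requested anchor")
  rows <- lapply(metric_cols, function(mc) {
    a <- pick[[mc]][pick$region == "cortical"]
    b <- pick[[mc]][pick$region == "bg"]
    if (length(a) < 2L || length(b) < 2L) stop_nccthist("need >= 2 subjects per group")
    tt <- pooled_t(a, b)
    av <- oneway_anova(list(a, b))
    ci <- bootstrap_ci(a, b, n_boot = n_boot, seed = seed)
    data.frame(metric = mc,
               n_cortical = length(a), n_bg = length(b),
               mean_cortical = mean(a), sd_cortical = stats::sd(a),
               mean_bg = mean(b), sd_bg = stats::sd(b),
               mean_difference = tt$mean_difference,
               F = av$F, p_anova = av$p,
               t = tt$t, p_raw = tt$p,
               cohens_d = cohens_d(a, b),
               ci_low = ci$low, ci_high = ci$high,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bonferroni(out$p_raw, m = max(m, nrow(out)))
  out$significant <- out$p_adjusted < alpha
  out
}
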