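ANCHOR_GRID <- c(0, 60, 81.5, 94, 120, 180)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Region templates for the synthetic cohort
#'
#' Encodes the study conditions the generator reproduces: per-region lesion
#' and normal-tissue (control) mean HU and within-ROI SD, the lesion SD /
#' entropy targets with their between-subject spreads, and the anchor
#' trajectories of both metrics over the standard scan grid
#' \{0, 60, 81.5, 94, 120, 180\} minutes post-onset. Cortical lesions are the
#' heterogeneous class (higher SD and entropy); basal-ganglia (BG) lesions
#' are more uniform.
#'
#' @param region `"cortical"` or `"bg"`.
#' @return a list of class `region_template`.
#' @export
region_template <- function(region = c("cortical", "bg")) {
  region <- match.arg(region)
  if (region == "cortical") {
    tpl <- list(
      region = "cortical",
      lesion_mean_hu = 26.71, control_mean_hu = 39.41, control_sd = 6.07,
      target_sd = 5.16, target_entropy = 4.34,
      bs_sd_of_sd = 1.17, bs_sd_of_entropy = 0.30,
      trajectory = data.frame(
        time_min = ANCHOR_GRID,
        sd_mean = c(5.16, 5.29, 5.38, 5.35, 5.30, 5.25),
        sd_bsd = c(1.17, 1.14, 1.15, 1.12, 1.10, 1.08),
        entropy_mean = c(4.34, 4.46, 4.52, 4.50, 4.47, 4.43),
        entropy_bsd = c(0.30, 0.29, 0.28, 0.27, 0.26, 0.25)))
  } else {
    tpl <- list(
      region = "bg",
      lesion_mean_hu = 25.93, control_mean_hu = 29.05, control_sd = 4.19,
      target_sd = 3.94, target_entropy = 3.99,
      bs_sd_of_sd = 0.46, bs_sd_of_entropy = 0.15,
      trajectory = data.frame(
        time_min = ANCHOR_GRID,
        sd_mean = c(3.94, 3.98, 4.03, 4.01, 3.99, 3.97),
        sd_bsd = c(0.46, 0.44, 0.43, 0.45, 0.47, 0.48),
        entropy_mean = c(3.99, 4.02, 4.05, 4.03, 4.01, 3.99),
        entropy_bsd = c(0.15, 0.14, 0.14, 0.15, 0.16, 0.17)))
  }
  structure(tpl, class = "region_template")
}

#' Synthetic cohort configuration
#'
#' Defaults are the study conditions: 27 cortical and 18 BG subjects, a mean
#' of 5.2 scans per subject on the standard anchor grid, a lesion-over-control
#' crossover planted in one third of cortical cases near 94 min, and 1e5
#' pixels per ROI (chosen for estimator stability; use ~500 for realistic-ROI
#' bias studies).
#'
#' @param n_cortical,n_bg group sizes (>= 2).
#' @param scans_per_subject target mean number of scans (baseline, peak and
#'   180-min anchors are always present; the rest are included with the
#'   probability that achieves this mean).
#' @param crossover_fraction_cortical fraction of cortical cases with a
#'   planted crossover (default 1/3).
#' @param pixels_per_roi pixels drawn per ROI per scan.
#' @param seed master seed (required); the whole cohort is a pure function of
#'   the config and this seed.
#' @param hu_offset_sd between-subject SD of the whole-head HU offset.
#' @param keep_samples keep raw pixel samples in each case (memory-heavy).
#' @param null_mode both groups share the BG template and no crossover is
#'   planted — a null cohort for type-I-error checks.
#' @param spec histogram binning spec used for calibration and metrics.
#' @param p_optional override for the optional-anchor inclusion probability
#'   (normally derived from `scans_per_subject`).
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(n_cortical = 27L, n_bg = 18L, scans_per_subject = 5.2,
                          crossover_fraction_cortical = 1 / 3,
                          pixels_per_roi = 1e5, seed,
                          hu_offset_sd = 4, keep_samples = FALSE,
                          null_mode = FALSE, spec = histogram_spec(),
                          p_optional = NULL) {
  if (missing(seed)) stop_nccthist("'seed' is required")
  n_cortical <- as.integer(n_cortical); n_bg <- as.integer(n_bg)
  if (n_cortical < 2L || n_bg < 2L) stop_nccthist("group sizes must be >= 2")
  if (crossover_fraction_cortical < 0 || crossover_fraction_cortical > 1)
    stop_nccthist("'crossover_fraction_cortical' must be in [0, 1]")
  structure(list(n_cortical = n_cortical, n_bg = n_bg,
                 scans_per_subject = scans_per_subject,
                 crossover_fraction_cortical = crossover_fraction_cortical,
                 pixels_per_roi = as.integer(pixels_per_roi),
                 seed = as.integer(seed), hu_offset_sd = hu_offset_sd,
                 keep_samples = keep_samples, null_mode = null_mode,
                 spec = spec, p_optional = p_optional),
            class = "cohort_config")
}

# ---- calibrated pmfs ------------------------------------------------------

bin_edges <- function(spec) seq(spec$hu_min, spec$hu_max, length.out = spec$n_bins + 1L)
bin_centers <- function(spec) {
  e <- bin_edges(spec)
  (e[-1L] + e[-length(e)]) / 2
}

# discretize a continuous cdf onto the spec's bins; tails are absorbed into
# the edge bins (the clip_to_range convention the sampler also uses)
discretize_cdf <- function(cdf, spec) {
  Fv <- cdf(bin_edges(spec))
  Fv[1L] <- 0; Fv[length(Fv)] <- 1
  p <- diff(Fv)
  p / sum(p)
}

mix_cdf <- function(family, mean_hu, knob, scale) {
  if (family == "location") {
    function(x) 0.5 * stats::pnorm(x, mean_hu - knob, scale) +
      0.5 * stats::pnorm(x, mean_hu + knob, scale)
  } else {  # scale mixture: same mean, sds scale/knob and scale*knob
    function(x) 0.5 * stats::pnorm(x, mean_hu, scale / knob) +
      0.5 * stats::pnorm(x, mean_hu, scale * knob)
  }
}

pmf_mean <- function(probs, spec) sum(probs * bin_centers(spec))
pmf_sd <- function(probs, spec) {
  c0 <- bin_centers(spec); m <- sum(probs * c0)
  sqrt(sum(probs * (c0 - m)^2))
}

new_calibrated_pmf <- function(probs, spec, params) {
  structure(list(probs = probs, spec = spec,
                 achieved_sd = pmf_sd(probs, spec),
                 achieved_entropy = entropy_from_probs(probs),
                 achieved_mean = pmf_mean(probs, spec),
                 params = params),
            class = "calibrated_pmf")
}

# inner calibration: find the component scale so the *pmf* SD hits target_sd
# exactly (discretization shifts the SD of the continuous mixture by
# ~ +h^2/12, so the continuous variance identity is only the starting point)
calibrate_scale_for_sd <- function(target_sd, mean_hu, spec, family = "location",
                                   knob = 0) {
  f <- function(s) pmf_sd(discretize_cdf(mix_cdf(family, mean_hu, knob, s), spec), spec) - target_sd
  lo <- 0.02; hi <- 40
  if (f(hi) < 0) stop_nccthist("target SD unreachable (too large for the histogram range)")
  if (f(lo) > 0) stop_nccthist("target SD unreachable given the mixture separation")
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Discretized-Gaussian pmf with a prescribed SD
#'
#' Single Gaussian centered at `mean_hu` whose *discretized* pmf has exactly
#' the requested SD. This is the maximum-entropy member of the calibration
#' family at that SD, so its entropy is the feasibility bound used by
#' [calibrate_joint_pmf()].
#'
#' @param target_sd SD in HU.
#' @param mean_hu pmf center in HU.
#' @param spec a [histogram_spec()].
#' @return a `calibrated_pmf`.
#' @export
calibrate_sd_pmf <- function(target_sd, mean_hu, spec = histogram_spec()) {
  s <- calibrate_scale_for_sd(target_sd, mean_hu, spec, "location", 0)
  p <- discretize_cdf(mix_cdf("location", mean_hu, 0, s), spec)
  new_calibrated_pmf(p, spec, list(family = "gaussian", mean_hu = mean_hu,
                                   sigma = s, delta = 0))
}

#' Maximum histogram entropy attainable at a given SD
#'
#' Entropy (bits) of the SD-calibrated discretized Gaussian — the Gaussian is
#' the maximum-entropy distribution at fixed variance, so no pixel
#' distribution binned under `spec` can jointly have this SD and more
#' entropy. For 1-HU bins and moderate SD this is close to the closed form
#' \eqn{\tfrac12 \log_2(2\pi e \sigma^2)}.
#'
#' @inheritParams calibrate_sd_pmf
#' @return entropy bound in bits.
#' @export
max_entropy_at_sd <- function(target_sd, mean_hu, spec = histogram_spec()) {
  calibrate_sd_pmf(target_sd, mean_hu, spec)$achieved_entropy
}

#' Discretized-Gaussian pmf with a prescribed entropy
#'
#' Bisects on the Gaussian sigma — histogram entropy of the discretized
#' Gaussian is strictly increasing in sigma over the working range — until
#' the pmf entropy matches `target_entropy` to within `tol` bits.
#'
#' @param target_entropy bits, in `(0, log2(n_bins))`.
#' @param mean_hu pmf center in HU.
#' @param spec a [histogram_spec()].
#' @param tol entropy tolerance in bits (default 1e-6).
#' @return a `calibrated_pmf`.
#' @export
calibrate_entropy_pmf <- function(target_entropy, mean_hu,
                                  spec = histogram_spec(), tol = 1e-6) {
  if (target_entropy <= 0) stop_nccthist("target entropy must be > 0")
  if (target_entropy >= log2(spec$n_bins))
    stop_nccthist("target entropy unreachable (uniform limit log2(n_bins))")
  H <- function(s) entropy_from_probs(discretize_cdf(mix_cdf("location", mean_hu, 0, s), spec))
  lo <- 0.02; hi <- 25
  if (H(hi) < target_entropy)
    stop_nccthist("target entropy unreachable within the histogram range")
  if (H(lo) > target_entropy)
    stop_nccthist("target entropy below the single-bin limit")
  s <- stats::uniroot(function(x) H(x) - target_entropy, c(lo, hi), tol = 1e-11)$root
  p <- discretize_cdf(mix_cdf("location", mean_hu, 0, s), spec)
  out <- new_calibrated_pmf(p, spec, list(family = "gaussian", mean_hu = mean_hu,
                                          sigma = s, delta = 0))
  if (abs(out$achieved_entropy - target_entropy) > tol)
    stop_nccthist("entropy calibration did not converge")
  out
}

# smallest pmf SD at which a given entropy is attainable (inverse bound)
min_sd_for_entropy <- function(target_entropy, mean_hu, spec = histogram_spec()) {
  calibrate_entropy_pmf(target_entropy, mean_hu, spec)$achieved_sd
}

#' Jointly calibrate a pixel pmf to an (SD, entropy) target pair
#'
#' Nested bisection over a symmetric two-component Gaussian mixture. The
#' inner loop fixes the mixture's shape knob and solves the component scale
#' so the discretized pmf's SD equals `target_sd` exactly; the outer loop
#' moves the knob — which lowers entropy at fixed SD — until the pmf entropy
#' equals `target_entropy`. Two families are available:
#' `"location"` (components at `mean_hu +- delta`, the bimodal default) and
#' `"scale"` (same mean, component sds `s/r` and `s*r`, heavy-tailed). Both
#' hit the same SD/entropy pair with opposite-signed excess kurtosis, which
#' the cohort generator exploits to keep third/fourth moments free of group
#' signal.
#'
#' The pair is feasible only if `target_entropy` does not exceed the Gaussian
#' maximum at `target_sd` (see [max_entropy_at_sd()]); infeasible requests
#' error with the bound.
#'
#' @param target_sd SD in HU.
#' @param target_entropy entropy in bits.
#' @param mean_hu pmf center in HU.
#' @param spec a [histogram_spec()].
#' @param family `"location"` or `"scale"`.
#' @param tol tolerance on achieved SD and entropy (default 1e-6).
#' @return a `calibrated_pmf` whose `achieved_sd` / `achieved_entropy` are
#'   re-evaluated from the final pmf.
#' @export
calibrate_joint_pmf <- function(target_sd, target_entropy, mean_hu,
                                spec = histogram_spec(),
                                family = c("location", "scale"), tol = 1e-6) {
  family <- match.arg(family)
  hmax <- max_entropy_at_sd(target_sd, mean_hu, spec)
  if (target_entropy > hmax + 1e-9)
    stop_nccthist(sprintf(
      "infeasible target pair: entropy %.4f bits exceeds the Gaussian maximum %.4f at SD %.4f",
      target_entropy, hmax, target_sd))
  if (target_entropy <= 0) stop_nccthist("target entropy must be > 0")
  pmf_at <- function(knob) {
    s <- calibrate_scale_for_sd(target_sd, mean_hu, spec, family, knob)
    list(probs = discretize_cdf(mix_cdf(family, mean_hu, knob, s), spec), scale = s)
  }
  if (hmax - target_entropy < tol) {   # degenerate: single Gaussian suffices
    out <- calibrate_sd_pmf(target_sd, mean_hu, spec)
    out$params$family <- family
    return(out)
  }
  knob_lo <- if (family == "location") 0 else 1
  knob_hi <- if (family == "location") sqrt(max(target_sd^2 - 0.3, 1e-4)) else 12
  # extreme knobs can make the inner SD calibration infeasible (near-spike
  # components); such knobs lie far beyond the root, so score them as
  # "entropy far below target" to keep the bracket valid
  g <- function(k) tryCatch(entropy_from_probs(pmf_at(k)$probs),
                            error = function(e) 0) - target_entropy
  if (g(knob_hi) > 0)
    stop_nccthist("target entropy unreachable: below the mixture family's range at this SD")
  k <- stats::uniroot(g, c(knob_lo, knob_hi), tol = 1e-10, maxiter = 200L)$root
  fit <- pmf_at(k)
  out <- new_calibrated_pmf(fit$probs, spec,
                            list(family = family, mean_hu = mean_hu,
                                 knob = k, scale = fit$scale))
  if (abs(out$achieved_sd - target_sd) > 1e-4 ||
      abs(out$achieved_entropy - target_entropy) > 1e-4)
    stop_nccthist("joint calibration did not converge to the requested tolerance")
  out
}

#' @export
print.calibrated_pmf <- function(x, ...) {
  cat(sprintf("calibrated pmf (%s): mean %.2f HU, sd %.4f HU, entropy %.4f bits\n",
              x$params$family, x$achieved_mean, x$achieved_sd, x$achieved_entropy))
  invisible(x)
}

#' Draw an ROI pixel sample from a calibrated pmf
#'
#' Draws i.i.d. bin indices from the pmf and adds uniform jitter within each
#' bin, so the sample's histogram under the same spec is exactly multinomial
#' in the pmf and the plug-in entropy recovers the calibrated value (up to
#' multinomial noise).
#'
#' @param pmf a `calibrated_pmf`.
#' @param n_px number of pixels (>= 1).
#' @param seed optional seed; when `NULL` the current RNG stream is used.
#' @param source_label,pixel_spacing passed to [hu_sample()].
#' @return an [hu_sample()].
#' @export
sample_roi <- function(pmf, n_px, seed = NULL, source_label = "lesion",
                       pixel_spacing = NULL) {
  stopifnot(inherits(pmf, "calibrated_pmf"))
  n_px <- as.integer(n_px)
  if (n_px < 1L) stop_nccthist("'n_px' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  spec <- pmf$spec
  w <- (spec$hu_max - spec$hu_min) / spec$n_bins
  bins <- sample.int(spec$n_bins, n_px, replace = TRUE, prob = pmf$probs)
  vals <- spec$hu_min + (bins - 1L) * w + stats::runif(n_px) * w
  hu_sample(vals, pixel_spacing = pixel_spacing, source_label = source_label)
}

# ---- case and cohort generation ------------------------------------------

scan_time_jitter <- function(anchor) {
  j <- switch(as.character(anchor),
              "0" = c(0, 4), "60" = c(-4, 4), "81.5" = c(-3, 3),
              "94" = c(-2, 2), "120" = c(-4, 4), "180" = c(-5, 5),
              c(-2, 2))
  anchor + stats::runif(1L, j[1L], j[2L])
}

# Per-scan (SD, entropy) targets for a standalone subject: the anchor curves
# shifted by the subject's heterogeneity factor (cohort generation instead
# interpolates the calibrated per-anchor targets from cohort_anchor_targets).
subject_targets <- function(template, z, t) {
  tr <- template$trajectory
  list(sd = max(interp_flat(t, tr$time_min, tr$sd_mean) +
                  z * interp_flat(t, tr$time_min, tr$sd_bsd), 0.6),
       entropy = max(interp_flat(t, tr$time_min, tr$entropy_mean) +
                       z * interp_flat(t, tr$time_min, tr$entropy_bsd), 0.2))
}

# closed-form minimum *sample* SD at which an entropy is attainable:
# invert maxH(s_pmf) ~ 0.5 log2(2 pi e (s_pmf^2 - w^2/12)) and add the
# sampler's jitter variance back (accurate to ~1e-3 bits for sigma >= 2;
# the per-scan projection in make_case is the exact safety net)
min_sample_sd_cf <- function(entropy, spec, headroom = 0.02) {
  w <- (spec$hu_max - spec$hu_min) / spec$n_bins
  sqrt(2^(2 * entropy) / (2 * pi * exp(1)) + w^2 / 6) + headroom
}

# Cohort target calibration: per anchor time, draw linear-in-z subject
# targets, project infeasible (SD, entropy) pairs onto the frontier
# preserving entropy, and iteratively re-center both vectors so their
# cohort means equal the anchor means. Entropy means are reproduced exactly;
# SD means are reproduced exactly wherever the anchor pair is jointly
# feasible on average, and otherwise settle at the smallest feasible excess
# (the frontier's hypograph is convex, so a cohort whose mean entropy
# exceeds the Gaussian bound at the mean SD cannot avoid that excess).
# Returns n_subjects x n_anchors matrices of adjusted targets; linear
# interpolation between anchors stays feasible by convexity.
cohort_anchor_targets <- function(template, z_vec, spec, iters = 8L) {
  tr <- template$trajectory
  n <- length(z_vec); K <- nrow(tr)
  sd_m <- matrix(NA_real_, n, K); e_m <- matrix(NA_real_, n, K)
  for (k in seq_len(K)) {
    sd_k <- pmax(tr$sd_mean[k] + z_vec * tr$sd_bsd[k], 0.6)
    e_k <- pmax(tr$entropy_mean[k] + z_vec * tr$entropy_bsd[k], 0.2)
    for (it in seq_len(iters)) {
      e_k <- pmax(e_k + (tr$entropy_mean[k] - mean(e_k)), 0.2)
      sd_k <- pmax(sd_k, min_sample_sd_cf(e_k, spec))
      sd_k <- pmax(sd_k + (tr$sd_mean[k] - mean(sd_k)), 0.6)
    }
    sd_k <- pmax(sd_k, min_sample_sd_cf(e_k, spec))
    sd_m[, k] <- sd_k; e_m[, k] <- e_k
  }
  list(time_min = tr$time_min, sd = sd_m, entropy = e_m)
}

# mean-HU curves; gap = lesion - control (negative: lesion hypodense)
case_mean_curves <- function(template, crossover, t_cross) {
  if (template$region == "bg") {
    control <- function(t) rep(29.05, length(t))
    gap <- function(t) interp_flat(t, c(0, 180), c(-3.12, -3.6))
  } else if (!crossover) {
    control <- function(t) rep(39.41, length(t))
    gap <- function(t) interp_flat(t, c(0, 180), c(-12.70, -13.2))
  } else {
    control <- function(t) interp_flat(t, c(0, 94, 180), c(39.41, 27.89, 27.5))
    kt <- c(0, 60, 81.5, t_cross, t_cross + 15, 180)
    kv <- c(-12.70, -4.0, -1.5, 0, 0.5, 0.8)
    gap <- function(t) interp_flat(t, kt, kv)
  }
  list(control = control, lesion = function(t) control(t) + gap(t))
}

# project an (sd, entropy) request onto the feasible region. The frontier is
# the Gaussian maximum-entropy curve; entropy — the primary biomarker and the
# quantity the anchor tables track most tightly — is preserved, and the SD is
# raised to the smallest value at which the entropy is attainable, plus a
# small headroom so the joint calibration has room to converge.
project_feasible <- function(sd, entropy, mean_hu, spec,
                             headroom = 0.02, margin_bits = 1e-3) {
  entropy <- max(entropy, 0.2)
  sd <- max(sd, 0.5)
  hmax <- max_entropy_at_sd(sd, mean_hu, spec)
  if (entropy <= hmax - margin_bits)
    return(list(sd = sd, entropy = entropy, clipped = FALSE))
  list(sd = min_sd_for_entropy(entropy, mean_hu, spec) + headroom,
       entropy = entropy, clipped = TRUE)
}

# the sampler adds uniform within-bin jitter (variance w^2/12), so a pmf
# meant to yield pixel samples of SD s must itself have SD sqrt(s^2 - w^2/12)
pmf_sd_request <- function(sample_sd_target, spec) {
  w <- (spec$hu_max - spec$hu_min) / spec$n_bins
  sqrt(max(sample_sd_target^2 - w^2 / 12, 0.09))
}

#' Generate one synthetic lesion case
#'
#' Draws a subject from a [region_template()]: scan times on the anchor grid
#' (baseline, 76–87-min peak and 180 min always present; 94 and 120 min also
#' present for crossover-flagged subjects so the crossing is bracketed by
#' scans; the rest included with probability `p`), per-scan lesion SD/entropy
#' targets obtained by shifting the anchor trajectories with the subject's
#' heterogeneity factor `z`, feasibility projection (see the vignette), a
#' jointly calibrated pixel pmf per scan, and a Gaussian control pmf at the
#' region's normal-tissue SD. If flagged, the lesion mean-HU trajectory
#' crosses the control at `94 +- 5` min and stays >= 0.5 HU above it from 15
#' min after the crossing.
#'
#' @param template a [region_template()].
#' @param config a [cohort_config()].
#' @param subject_seed integer seed for this subject.
#' @param z subject heterogeneity factor (drawn `N(0,1)` when `NULL`);
#'   multiplies the between-subject SD columns of the anchor trajectories.
#' @param crossover plant a lesion-over-control crossover?
#' @param shape_family mixture family for the lesion pmf (`"location"` or
#'   `"scale"`); drawn at random when `NULL` so that skewness/kurtosis carry
#'   no systematic group signal.
#' @param anchor_targets optional calibrated per-anchor targets for this
#'   subject (a list with `time_min`, `sd`, `entropy` vectors, one row of
#'   the cohort calibration); when `NULL` the linear draw from `z` is used.
#' @param case_id identifier used in the metric rows.
#' @return a list of class `lesion_case`: metric rows (`$metrics`), ground
#'   truth (`$truth`), clip events, and optionally raw samples.
#' @export
make_case <- function(template, config, subject_seed, z = NULL,
                      crossover = FALSE, shape_family = NULL,
                      anchor_targets = NULL, case_id = "case") {
  stopifnot(inherits(template, "region_template"), inherits(config, "cohort_config"))
  set.seed(as.integer(subject_seed))
  if (is.null(z)) z <- stats::rnorm(1L)
  if (is.null(shape_family)) shape_family <- sample(c("location", "scale"), 1L)
  u <- stats::rnorm(1L, 0, config$hu_offset_sd)
  t_cross <- if (crossover) 94 + stats::runif(1L, -5, 5) else NA_real_

  mandatory <- if (crossover) c(0, 81.5, 94, 120, 180) else c(0, 81.5, 180)
  optional <- setdiff(ANCHOR_GRID, mandatory)
  p_opt <- config$p_optional %||%
    clamp((config$scans_per_subject - length(mandatory)) / max(length(optional), 1L), 0, 1)
  anchors <- sort(c(mandatory, optional[stats::runif(length(optional)) < p_opt]))
  times <- vapply(anchors, scan_time_jitter, numeric(1))

  curves <- case_mean_curves(template, crossover, t_cross)
  spec <- config$spec
  rows <- list(); clips <- list(); samples <- list()
  control_pmf_cache <- NULL
  sd_control <- max(template$control_sd + z * template$bs_sd_of_sd, 0.8)

  for (i in seq_along(times)) {
    t <- times[i]
    tg <- if (is.null(anchor_targets)) subject_targets(template, z, t) else
      list(sd = interp_flat(t, anchor_targets$time_min, anchor_targets$sd),
           entropy = interp_flat(t, anchor_targets$time_min, anchor_targets$entropy))
    pr <- project_feasible(pmf_sd_request(tg$sd, spec), tg$entropy,
                           curves$lesion(t) + u, spec)
    if (pr$clipped)
      clips[[length(clips) + 1L]] <- data.frame(
        case_id = case_id, time_min = t,
        requested_sd = tg$sd, adjusted_pmf_sd = pr$sd, entropy = pr$entropy)
    lesion_pmf <- calibrate_joint_pmf(pr$sd, pr$entropy,
                                      curves$lesion(t) + u,
                                      spec, family = shape_family)
    ctrl_mean <- curves$control(t) + u
    if (is.null(control_pmf_cache) ||
        abs(control_pmf_cache$achieved_mean - ctrl_mean) > 1e-9)
      control_pmf_cache <- calibrate_sd_pmf(pmf_sd_request(sd_control, spec),
                                            ctrl_mean, spec)
    les <- sample_roi(lesion_pmf, config$pixels_per_roi, source_label = "lesion")
    ctl <- sample_roi(control_pmf_cache, config$pixels_per_roi, source_label = "control")
    rows[[2L * i - 1L]] <- metric_row(case_id, template$region, "lesion", t,
                                      metric_set(les, spec))
    rows[[2L * i]] <- metric_row(case_id, template$region, "control", t,
                                 metric_set(ctl, spec))
    if (config$keep_samples) samples[[as.character(t)]] <- list(lesion = les, control = ctl)
  }

  structure(list(
    case_id = case_id, region = template$region,
    metrics = do.call(rbind, rows),
    clip_events = if (length(clips)) do.call(rbind, clips) else NULL,
    samples = if (config$keep_samples) samples else NULL,
    truth = list(z = z, hu_offset = u, shape_family = shape_family,
                 crossover_planted = crossover, t_cross = t_cross,
                 times = times, subject_seed = as.integer(subject_seed))),
    class = "lesion_case")
}

#' Generate the full synthetic cohort
#'
#' Produces `n_cortical + n_bg` cases with deterministic per-subject seeds
#' derived from the master seed. Subject heterogeneity factors are drawn as
#' exactly centered and standardized normals within each group, so the
#' cohort's cross-sectional mean and SD of each metric target reproduce the
#' anchor tables by construction; exactly
#' `round(crossover_fraction_cortical * n_cortical)` cortical cases are
#' flagged for a crossover. The manifest records every ground-truth
#' parameter (factors, flags, planted crossover times, shape families, scan
#' times, feasibility clips) for recovery tests.
#'
#' @param config a [cohort_config()].
#' @return a list of class `ais_cohort` with `$metrics` (long-format
#'   data.frame, see [metric_row()]) and `$manifest`.
#' @export
make_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  center <- function(n) { x <- stats::rnorm(n); as.numeric(scale(x)) }
  z_c <- center(config$n_cortical)
  z_b <- center(config$n_bg)
  n_cross <- if (config$null_mode) 0L else
    as.integer(round(config$crossover_fraction_cortical * config$n_cortical))
  cross_ids <- if (n_cross > 0L) sort(sample.int(config$n_cortical, n_cross)) else integer(0)

  tpl_c <- if (config$null_mode) region_template("bg") else region_template("cortical")
  if (config$null_mode) tpl_c$region <- "cortical"
  tpl_b <- region_template("bg")
  at_c <- cohort_anchor_targets(tpl_c, z_c, config$spec)
  at_b <- cohort_anchor_targets(tpl_b, z_b, config$spec)

  # optional-anchor probability solving the cohort-mean scan count
  n_mand <- 5L * n_cross + 3L * (config$n_cortical - n_cross) + 3L * config$n_bg
  n_opt <- 1L * n_cross + 3L * (config$n_cortical - n_cross) + 3L * config$n_bg
  p_opt <- config$p_optional %||%
    clamp((config$scans_per_subject * (config$n_cortical + config$n_bg) - n_mand) / n_opt, 0, 1)
  config$p_optional <- p_opt

  base <- config$seed %% 1000000L
  cases <- vector("list", config$n_cortical + config$n_bg)
  k <- 0L
  for (i in seq_len(config$n_cortical)) {
    k <- k + 1L
    cases[[k]] <- make_case(tpl_c, config, subject_seed = base * 1000L + k,
                            z = z_c[i], crossover = i %in% cross_ids,
                            anchor_targets = list(time_min = at_c$time_min,
                                                  sd = at_c$sd[i, ],
                                                  entropy = at_c$entropy[i, ]),
                            case_id = sprintf("C%02d", i))
  }
  for (i in seq_len(config$n_bg)) {
    k <- k + 1L
    cases[[k]] <- make_case(tpl_b, config, subject_seed = base * 1000L + k,
                            z = z_b[i], crossover = FALSE,
                            anchor_targets = list(time_min = at_b$time_min,
                                                  sd = at_b$sd[i, ],
                                                  entropy = at_b$entropy[i, ]),
                            case_id = sprintf("B%02d", i))
  }

  metrics <- do.call(rbind, lapply(cases, `[[`, "metrics"))
  rownames(metrics) <- NULL
  clip_events <- do.call(rbind, lapply(cases, `[[`, "clip_events"))
  manifest <- list(
    config = config[c("n_cortical", "n_bg", "scans_per_subject",
                      "crossover_fraction_cortical", "pixels_per_roi", "seed",
                      "hu_offset_sd", "null_mode", "p_optional")],
    n_crossover_planted = n_cross,
    crossover_case_ids = sprintf("C%02d", cross_ids),
    cases = lapply(cases, function(cs) c(list(case_id = cs$case_id,
                                              region = cs$region), cs$truth)),
    clip_events = clip_events)
  structure(list(metrics = metrics, manifest = manifest,
                 cases = if (config$keep_samples) cases else NULL),
            class = "ais_cohort")
}

#' @export
print.ais_cohort <- function(x, ...) {
  cat(sprintf("synthetic AIS cohort: %d metric rows, %d cases (%d crossover planted)\n",
              nrow(x$metrics), length(x$manifest$cases),
              x$manifest$n_crossover_planted))
  invisible(x)
}

#' Cohort with group separation injected only inside one time window
#'
#' A validation cohort for the sliding-window detector: both groups share the
#' BG-like pixel distribution at every scan except that cortical lesions
#' switch to the cortical SD/entropy targets for scans falling inside
#' `window`. Scan times are fixed (no jitter) at
#' `{0, 30, 60, 75, 76, 81.5, 87, 88, 120, 180}` for every subject, so the
#' injected window `[76, 88)` is the unique 12-min window containing all of
#' — and nothing but — the divergent scans.
#'
#' @param seed master seed.
#' @param n_cortical,n_bg group sizes.
#' @param pixels_per_roi pixels per ROI (default 2e4).
#' @param window the injected window, default `c(76, 88)`.
#' @return a long-format metrics data.frame.
#' @export
make_window_probe_cohort <- function(seed, n_cortical = 27L, n_bg = 18L,
                                     pixels_per_roi = 2e4, window = c(76, 88)) {
  set.seed(as.integer(seed))
  spec <- histogram_spec()
  times <- c(0, 30, 60, 75, 76, 81.5, 87, 88, 120, 180)
  zs <- c(as.numeric(scale(stats::rnorm(n_cortical))),
          as.numeric(scale(stats::rnorm(n_bg))))
  region <- rep(c("cortical", "bg"), c(n_cortical, n_bg))
  ids <- c(sprintf("C%02d", seq_len(n_cortical)), sprintf("B%02d", seq_len(n_bg)))
  base <- list(sd = 3.94, ent = 3.99, bsd_sd = 0.30, bsd_ent = 0.10)
  burst <- list(sd = 5.16, ent = 4.34)
  rows <- list()
  for (s in seq_along(ids)) {
    z <- zs[s]
    sd0 <- base$sd + z * base$bsd_sd
    en0 <- base$ent + z * base$bsd_ent
    pr0 <- project_feasible(pmf_sd_request(sd0, spec), en0, 25.93, spec)
    pmf_base <- calibrate_joint_pmf(pr0$sd, pr0$entropy, 25.93, spec)
    pmf_burst <- if (region[s] == "cortical") {
      prb <- project_feasible(pmf_sd_request(burst$sd + z * base$bsd_sd, spec),
                              burst$ent + z * base$bsd_ent, 25.93, spec)
      calibrate_joint_pmf(prb$sd, prb$entropy, 25.93, spec)
    } else pmf_base
    pmf_ctl <- calibrate_sd_pmf(pmf_sd_request(4.19, spec), 29.05, spec)
    for (t in times) {
      inw <- region[s] == "cortical" && t >= window[1L] && t < window[2L]
      pmf <- if (inw) pmf_burst else pmf_base
      les <- sample_roi(pmf, pixels_per_roi, source_label = "lesion")
      ctl <- sample_roi(pmf_ctl, pixels_per_roi, source_label = "control")
      rows[[length(rows) + 1L]] <- metric_row(ids[s], region[s], "lesion", t,
                                              metric_set(les, spec))
      rows[[length(rows) + 1L]] <- metric_row(ids[s], region[s], "control", t,
                                              metric_set(ctl, spec))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---- phantom rasterization ------------------------------------------------

#' Rasterize one scan into a symmetric head phantom
#'
#' Builds a 2-D phantom: air background (-1000 HU), a bright skull ring, a
#' brain disc filled from the control pmf, and a circular lesion filled from
#' the lesion pmf, lateralized so its mirror about the exact midline lies in
#' normal tissue. The grid is odd-sized so the midline is an integer column
#' and mirroring is an exact involution. The lesion radius is chosen to
#' satisfy the 1 cm^2 minimum-area rule at the phantom's pixel spacing.
#'
#' @param lesion_pmf,control_pmf `calibrated_pmf` objects.
#' @param grid odd image size in pixels (default 255).
#' @param fov_mm field of view in mm (default 250, i.e. ~0.98 mm pixels).
#' @param lesion_radius_px lesion radius in pixels (default 12).
#' @param seed optional RNG seed.
#' @return list with `plane` ([image_plane()], midline set), `lesion_mask`
#'   and `control_mask` ([roi_mask()]).
#' @export
rasterize_scan <- function(lesion_pmf, control_pmf, grid = 255L, fov_mm = 250,
                           lesion_radius_px = 12L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grid <- as.integer(grid)
  if (grid %% 2L == 0L) stop_nccthist("'grid' must be odd (integer midline)")
  sp <- fov_mm / grid
  mid <- (grid + 1L) %/% 2L
  rr <- row(matrix(0, grid, grid)) - mid
  cc <- col(matrix(0, grid, grid)) - mid
  d2 <- rr^2 + cc^2
  r_head <- 0.45 * grid; r_skull <- 0.42 * grid
  img <- matrix(-1000, grid, grid)
  img[d2 <= r_head^2] <- 700                      # skull ring
  brain <- d2 <= r_skull^2
  img[brain] <- sample_roi(control_pmf, sum(brain))$values
  lc <- mid + as.integer(round(0.2 * grid))       # lesion center column (lateral)
  dl2 <- (row(img) - mid)^2 + (col(img) - lc)^2
  lesion <- dl2 <= lesion_radius_px^2
  img[lesion] <- sample_roi(lesion_pmf, sum(lesion))$values
  region <- if (inherits(lesion_pmf, "calibrated_pmf")) "cortical" else "cortical"
  lmask <- roi_mask(lesion, label = "lesion", region = region)
  plane <- image_plane(img, spacing_mm = c(sp, sp), midline_col = mid)
  list(plane = plane, lesion_mask = lmask,
       control_mask = mirror_mask(lmask, mid))
}
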