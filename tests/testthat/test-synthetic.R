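# Re-evaluation oracles for the calibrated pmfs live in helper-oracles.R:
# oracle_entropy / oracle_pmf_sd recompute SD and entropy from the returned
# probability vector independently of the calibration path.

test_that("entropy calibration converges and is independently re-evaluable", {
  p <- calibrate_entropy_pmf(4.34, 26.71)
  expect_equal(oracle_entropy(p$probs), 4.34, tolerance = 1e-6)
  expect_equal(sum(p$probs), 1, tolerance = 1e-12)
  # sigma for the Gaussian closed-form entropy 4.415 is ~5.16
  p2 <- calibrate_entropy_pmf(4.415, 26.71)
  expect_equal(p2$params$sigma, sqrt(2^(2 * 4.415) / (2 * pi * exp(1))),
               tolerance = 0.02)
  expect_equal(p2$params$sigma, 5.16, tolerance = 0.05)
  # near-zero target concentrates in a single bin
  p3 <- calibrate_entropy_pmf(0.1, 26.71)
  expect_gt(max(p3$probs), 0.95)
  expect_error(calibrate_entropy_pmf(log2(100), 26.71), "unreachable")
  expect_error(calibrate_entropy_pmf(-1, 26.71), "> 0")
})

test_that("discretized-Gaussian entropy is strictly increasing in sigma", {
  sig <- seq(0.5, 15, by = 0.5)
  H <- vapply(sig, function(s) oracle_entropy(oracle_gaussian_pmf(26.71, s)),
              numeric(1))
  expect_true(all(diff(H) > 0))
})

test_that("joint calibration hits both targets in both mixture families", {
  for (fam in c("location", "scale")) {
    for (tg in list(c(5.16, 4.34, 26.71), c(3.94, 3.99, 25.93))) {
      p <- calibrate_joint_pmf(tg[1], tg[2], tg[3], family = fam)
      expect_equal(oracle_pmf_sd(p$probs), tg[1], tolerance = 1e-4)
      expect_equal(oracle_entropy(p$probs), tg[2], tolerance = 1e-4)
      expect_equal(sum(p$probs), 1, tolerance = 1e-12)
    }
  }
  # the two families sit on opposite sides of the Gaussian in excess kurtosis
  pl <- calibrate_joint_pmf(5.16, 4.34, 26.71, family = "location")
  ps <- calibrate_joint_pmf(5.16, 4.34, 26.71, family = "scale")
  kurt_of <- function(p) {
    ctr <- seq(-39.5, 59.5, 1); m <- sum(p$probs * ctr)
    v <- sum(p$probs * (ctr - m)^2)
    sum(p$probs * (ctr - m)^4) / v^2 - 3
  }
  expect_lt(kurt_of(pl), -0.2)
  expect_gt(kurt_of(ps), 0.2)
})

test_that("the max-entropy feasibility bound is enforced at the boundary", {
  hmax <- max_entropy_at_sd(3.94, 25.93)
  expect_equal(hmax, 0.5 * log2(2 * pi * exp(1) * (3.94^2 - 1 / 12)),
               tolerance = 5e-3)  # Sheppard-corrected closed form
  expect_error(calibrate_joint_pmf(3.94, hmax + 0.01, 25.93), "infeasible")
  # at the boundary the calibration degenerates to the single Gaussian
  pb <- calibrate_joint_pmf(3.94, hmax, 25.93)
  expect_equal(oracle_entropy(pb$probs), hmax, tolerance = 1e-4)
  expect_equal(oracle_pmf_sd(pb$probs), 3.94, tolerance = 1e-4)
})

test_that("ROI sampling is reproducible and recovers the calibrated targets", {
  p <- calibrate_joint_pmf(5.16, 4.34, 26.71)
  s1 <- sample_roi(p, 1000, seed = 9)
  s2 <- sample_roi(p, 1000, seed = 9)
  expect_identical(s1$values, s2$values)
  s3 <- sample_roi(p, 1)
  expect_length(s3$values, 1L)
  expect_true(s3$values >= -40 && s3$values <= 60)
  big <- sample_roi(p, 1e5, seed = 2)
  ms <- metric_set(big)
  expect_equal(ms$sd, 5.16, tolerance = 0.03)        # + within-bin jitter
  expect_equal(ms$entropy_bits, 4.34, tolerance = 0.02)
  expect_equal(ms$mean_hu, 26.71, tolerance = 0.05)
})

test_that("single cases plant (or withhold) the crossover as flagged", {
  cfg <- cohort_config(seed = 50, pixels_per_roi = 5000)
  cs <- make_case(region_template("cortical"), cfg, subject_seed = 501,
                  crossover = TRUE, case_id = "CX")
  ev <- detect_crossover(as_trajectories(cs$metrics)[[1]])
  expect_true(ev$occurred)
  expect_lt(abs(ev$time_min - 94), 10)
  csb <- make_case(region_template("bg"), cfg, subject_seed = 502, case_id = "BX")
  expect_false(detect_crossover(as_trajectories(csb$metrics)[[1]])$occurred)
  # deterministic in the subject seed
  cs2 <- make_case(region_template("cortical"), cfg, subject_seed = 501,
                   crossover = TRUE, case_id = "CX")
  expect_identical(cs$metrics, cs2$metrics)
})

test_that("cohort generation: counts, planted crossovers, determinism, manifest", {
  cfg <- cohort_config(n_cortical = 6, n_bg = 4, pixels_per_roi = 2000, seed = 33)
  co <- make_cohort(cfg)
  expect_equal(length(co$manifest$cases), 10L)
  expect_equal(co$manifest$n_crossover_planted, round(6 / 3))
  expect_equal(length(unique(co$metrics$case_id)), 10L)
  expect_true(all(co$metrics$role %in% c("lesion", "control")))
  # pure function of config + seed (byte-identical manifest and metrics)
  co2 <- make_cohort(cfg)
  expect_identical(co$metrics, co2$metrics)
  expect_identical(jsonlite::toJSON(co$manifest, auto_unbox = TRUE, digits = NA),
                   jsonlite::toJSON(co2$manifest, auto_unbox = TRUE, digits = NA))
  # every subject has at least baseline, peak-window and 180-min scans
  for (tr in as_trajectories(co$metrics)) {
    expect_gte(nrow(tr$points), 3L)
    expect_true(any(tr$points$time_min < 15))
    expect_true(any(tr$points$time_min >= 76 & tr$points$time_min < 88))
  }
})

test_that("null-mode cohorts show no significant metric after correction", {
  co <- make_cohort(cohort_config(n_cortical = 8, n_bg = 6, pixels_per_roi = 3000,
                                  seed = 12, null_mode = TRUE))
  cmp <- compare_cohort(co$metrics, n_boot = 200, seed = 12)
  expect_false(any(cmp$significant))
})

test_that("phantom rasterization honors the area and mirroring contracts", {
  pl <- calibrate_joint_pmf(5.16, 4.34, 26.71)
  pc <- calibrate_sd_pmf(6.07, 39.41)
  ph <- rasterize_scan(pl, pc, seed = 3)
  expect_true(roi_area_ok(ph$lesion_mask, ph$plane$spacing_mm))
  expect_equal(sum(ph$control_mask$mask), sum(ph$lesion_mask$mask))
  expect_false(any(ph$control_mask$mask & ph$lesion_mask$mask))
  back <- mirror_mask(ph$control_mask, ph$plane$midline_col)
  expect_identical(back$mask, ph$lesion_mask$mask)
  # the phantom's estimated midline matches the construction
  expect_equal(estimate_midline(ph$plane), ph$plane$midline_col)
  # lesion pixels reproduce the calibrated distribution
  ms <- metric_set(extract_sample(ph$plane, ph$lesion_mask))
  expect_equal(ms$mean_hu, 26.71, tolerance = 1)
  expect_equal(ms$sd, 5.16, tolerance = 0.6)
})
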