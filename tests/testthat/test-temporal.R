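template_metrics <- function() {
  # noise-free cohort following the anchor trajectories exactly (2 subjects
  # per region so group statistics are defined)
  tc <- region_template("cortical")$trajectory
  tb <- region_template("bg")$trajectory
  rbind(
    do.call(rbind, lapply(c("C01", "C02"), function(id)
      fake_rows(id, "cortical", tc$time_min, lesion_hu = 26.71,
                control_hu = 39.41, lesion_sd = tc$sd_mean,
                lesion_entropy = tc$entropy_mean))),
    do.call(rbind, lapply(c("B01", "B02"), function(id)
      fake_rows(id, "bg", tb$time_min, lesion_hu = 25.93, control_hu = 29.05,
                lesion_sd = tb$sd_mean, lesion_entropy = tb$entropy_mean))))
}

test_that("percent decrease reproduces the worked examples exactly", {
  expect_equal(percent_decrease(29.05, 25.93), 10.7)
  expect_equal(percent_decrease(39.41, 26.71), 32.2)
  expect_equal(percent_decrease(123.4, 123.4), 0)
  expect_error(percent_decrease(0, 5), "zero baseline")
  # unrounded value agrees with direct arithmetic
  expect_equal(percent_decrease(29.05, 25.93, digits = NULL),
               100 * (29.05 - 25.93) / 29.05, tolerance = 1e-12)
})

test_that("HU gap is control minus lesion and antisymmetric under role swap", {
  expect_equal(hu_gap(39.41, 26.71), 12.70)
  expect_equal(hu_gap(5, 5), 0)
  expect_equal(hu_gap(26.71, 39.41), -hu_gap(39.41, 26.71))
  expect_equal(hu_gap(list(control_mean_hu = 39.41, lesion_mean_hu = 26.71)), 12.70)
  expect_equal(hu_gap(39.41, 26.71),
               (39.41 - 26.71), tolerance = 1e-12)
})

test_that("crossover detection interpolates the zero crossing", {
  tr <- as_trajectories(fake_rows("X", "cortical", c(60, 120),
                                  lesion_hu = c(30, 31), control_hu = c(32, 30)))[[1]]
  ev <- detect_crossover(tr)       # gap -2 then +1: zero at 60 + 60 * 2/3
  expect_true(ev$occurred)
  expect_equal(ev$time_min, 100)
  # always negative: no event
  tr2 <- as_trajectories(fake_rows("X", "bg", c(0, 60, 120),
                                   lesion_hu = c(26, 25, 25), control_hu = c(29, 29, 29)))[[1]]
  expect_false(detect_crossover(tr2)$occurred)
  # exact zero at a scan time reports that scan time
  tr3 <- as_trajectories(fake_rows("X", "cortical", c(0, 90, 150),
                                   lesion_hu = c(25, 28, 29), control_hu = c(30, 28, 28)))[[1]]
  expect_equal(detect_crossover(tr3)$time_min, 90)
  # first event reported; later scans do not move it
  tr4 <- as_trajectories(fake_rows("X", "cortical", c(0, 90, 150, 200),
                                   lesion_hu = c(25, 29, 27, 30),
                                   control_hu = c(30, 28, 28, 28)))[[1]]
  expect_equal(detect_crossover(tr4)$time_min,
               detect_crossover(as_trajectories(
                 fake_rows("X", "cortical", c(0, 90),
                           lesion_hu = c(25, 29), control_hu = c(30, 28)))[[1]])$time_min)
  expect_error(detect_crossover(as_trajectories(
    fake_rows("X", "cortical", 60, 30, 32))[[1]]), ">= 2")
})

test_that("crossover fraction counts per region with display rounding", {
  mk <- function(id, region, crossed) {
    fake_rows(id, region, c(0, 90, 180),
              lesion_hu = if (crossed) c(25, 28, 29) else c(25, 25, 25),
              control_hu = c(30, 27.5, 28))
  }
  rows <- do.call(rbind, c(
    lapply(1:27, function(i) mk(sprintf("C%02d", i), "cortical", i <= 9)),
    lapply(1:18, function(i) mk(sprintf("B%02d", i), "bg", FALSE))))
  expect_equal(crossover_fraction(rows, "cortical"), 33.3)
  expect_equal(crossover_fraction(rows, "bg"), 0)
  all_cross <- do.call(rbind, lapply(1:27, function(i)
    mk(sprintf("C%02d", i), "cortical", TRUE)))
  expect_equal(crossover_fraction(all_cross, "cortical"), 100)
  expect_error(crossover_fraction(all_cross, "bg"), "no cases")
})

test_that("trajectory deltas recover the anchor-table changes on the template", {
  m <- template_metrics()
  expect_equal(trajectory_deltas(m, "entropy_bits", 0, 81.5, region = "cortical"),
               4.52 - 4.34, tolerance = 1e-12)
  expect_equal(trajectory_deltas(m, "sd", 0, 81.5, region = "bg"),
               4.03 - 3.94, tolerance = 1e-12)
  # flat trajectory
  flat <- fake_rows("F1", "bg", c(0, 80, 160), 25, 29, lesion_sd = 4, lesion_entropy = 4)
  expect_equal(trajectory_deltas(flat, "sd", 0, 160), 0)
  # unmatched anchors excluded with a warning; all excluded errors
  expect_warning(
    d <- trajectory_deltas(rbind(m, fake_rows("C99", "cortical", c(0, 200), 26, 39)),
                           "entropy_bits", 0, 81.5, region = "cortical"),
    "excluded")
  expect_equal(d, 4.52 - 4.34, tolerance = 1e-12)
  expect_error(suppressWarnings(trajectory_deltas(flat, "sd", 500, 700)),
               "no scans near|all subjects excluded")
})

test_that("template trajectories peak inside 76-87 min and decline after the crossover", {
  for (rg in c("cortical", "bg")) {
    tr <- region_template(rg)$trajectory
    peak_idx <- which.max(tr$entropy_mean)
    expect_true(tr$time_min[peak_idx] >= 76 && tr$time_min[peak_idx] <= 87)
    expect_equal(which.max(tr$sd_mean), peak_idx)
    after <- tr$time_min > 94
    expect_true(all(diff(tr$entropy_mean[after]) <= 0))
    expect_true(all(diff(tr$sd_mean[after]) <= 0))
  }
})

test_that("window scan contracts: ranking, shift equivariance, null cohort", {
  m <- template_metrics()
  # per-subject noise so group t-tests are defined
  set.seed(21)
  jit <- function(df) { df$sd <- df$sd + rnorm(nrow(df), 0, 0.2)
                        df$entropy_bits <- df$entropy_bits + rnorm(nrow(df), 0, 0.05); df }
  m4 <- jit(do.call(rbind, lapply(1:4, function(k) {
    d <- template_metrics(); d$case_id <- paste0(d$case_id, "_", k); d })))
  ws <- window_scan(m4, width = 12, step = 6)
  expect_s3_class(ws, "window_scan")
  expect_true(all(ws$score[1] <= ws$score))
  expect_true(all(ws$end_min - ws$start_min == 12))
  # time shift moves the windows with the cohort
  m4s <- m4; m4s$time_min <- m4s$time_min + 30
  ws_s <- window_scan(m4s, width = 12, step = 6)
  expect_equal(ws_s$start_min[1], ws$start_min[1] + 30)
  expect_equal(ws_s$score[1], ws$score[1], tolerance = 1e-9)
  # identical groups: nothing survives Bonferroni at the family level
  null_m <- m4
  null_m$sd <- 4 + rnorm(nrow(null_m), 0, 0.3)
  null_m$entropy_bits <- 4 + rnorm(nrow(null_m), 0, 0.1)
  ws_null <- window_scan(null_m, width = 12, step = 6)
  expect_gt(min(bonferroni(ws_null$score, m = max(4, nrow(ws_null)))), 0.05)
  expect_error(window_scan(m4, width = 1, step = 2), "width >= step")
})
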