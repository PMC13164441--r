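#' Per-subject metric trajectories
#'
#' A trajectory is one subject's time-sorted sequence of paired
#' lesion/control metric sets. [as_trajectories()] builds the list from the
#' long-format metrics table: rows are matched lesion/control per
#' `(case_id, time_min)` and spread into `lesion_*` / `control_*` columns.
#'
#' @param case_id subject id.
#' @param region `"cortical"` or `"bg"`.
#' @param points data.frame with column `time_min` (strictly increasing) and
#'   paired metric columns `lesion_mean_hu`, `control_mean_hu`, `lesion_sd`,
#'   `lesion_entropy_bits`, ...
#' @return an object of class `trajectory`.
#' @export
trajectory <- function(case_id, region, points) {
  if (!is.data.frame(points) || !"time_min" %in% names(points))
    stop_nccthist("'points' must be a data.frame with a 'time_min' column")
  if (any(points$time_min < 0)) stop_nccthist("times must be >= 0")
  if (is.unsorted(points$time_min, strictly = TRUE))
    stop_nccthist("times must be strictly increasing")
  structure(list(case_id = case_id, region = region, points = points),
            class = "trajectory")
}

#' @rdname trajectory
#' @param metrics long-format metrics data.frame (see [metric_row()]).
#' @export
as_trajectories <- function(metrics) {
  if (inherits(metrics, "trajectory")) return(list(metrics))
  if (is.list(metrics) && !is.data.frame(metrics) &&
      all(vapply(metrics, inherits, logical(1), "trajectory"))) return(metrics)
  stopifnot(is.data.frame(metrics))
  vals <- c("n_pixels", "mean_hu", "sd", "skewness", "kurtosis_excess", "entropy_bits")
  lapply(split(metrics, metrics$case_id), function(d) {
    les <- d[d$role == "lesion", , drop = FALSE]
    ctl <- d[d$role == "control", , drop = FALSE]
    pts <- data.frame(time_min = sort(unique(d$time_min)))
    for (v in vals) {
      pts[[paste0("lesion_", v)]] <- les[[v]][match(pts$time_min, les$time_min)]
      pts[[paste0("control_", v)]] <- ctl[[v]][match(pts$time_min, ctl$time_min)]
    }
    trajectory(d$case_id[1L], d$region[1L], pts)
  })
}

#' Percent decrease of mean HU from baseline tissue to lesion
#'
#' `100 * (baseline - lesion) / baseline`, reported to one decimal by
#' default (`digits = NULL` returns the unrounded value).
#'
#' @param baseline_mean,lesion_mean mean HU values; baseline must be nonzero.
#' @param digits decimals for display rounding (default 1).
#' @return percent decrease.
#' @export
percent_decrease <- function(baseline_mean, lesion_mean, digits = 1) {
  assert_number(baseline_mean, "baseline_mean")
  assert_number(lesion_mean, "lesion_mean")
  if (baseline_mean == 0) stop_nccthist("zero baseline mean")
  out <- 100 * (baseline_mean - lesion_mean) / baseline_mean
  if (is.null(digits)) out else round(out, digits)
}

#' Lesion-control HU gap
#'
#' `control - lesion` mean HU: positive when the lesion is hypodense
#' relative to its mirrored control. Accepts two numbers or a trajectory
#' point row carrying `control_mean_hu` / `lesion_mean_hu`.
#'
#' @param control_mean_hu control mean HU, or a list/data.frame row with both
#'   fields.
#' @param lesion_mean_hu lesion mean HU.
#' @return gap in HU.
#' @export
hu_gap <- function(control_mean_hu, lesion_mean_hu = NULL) {
  if (is.null(lesion_mean_hu)) {
    p <- control_mean_hu
    return(p$control_mean_hu - p$lesion_mean_hu)
  }
  control_mean_hu - lesion_mean_hu
}

#' Detect a lesion-over-control mean-HU crossover
#'
#' The signed gap `g(t) = lesion - control` mean HU starts negative in an
#' ischemic lesion; a crossover is the first time `g` reaches >= 0 from a
#' previously negative scan, with the crossing time linearly interpolated
#' between the bracketing scans (a scan with `g = 0` exactly reports that
#' scan time). A trajectory whose gap never turns non-negative after being
#' negative has no event.
#'
#' @param traj a [trajectory()] (>= 2 time points with both roles present).
#' @return list with `occurred` and, when occurred, `time_min`.
#' @export
detect_crossover <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  p <- traj$points
  keep <- !is.na(p$lesion_mean_hu) & !is.na(p$control_mean_hu)
  p <- p[keep, , drop = FALSE]
  if (nrow(p) < 2L) stop_nccthist("crossover detection needs >= 2 paired time points")
  g <- p$lesion_mean_hu - p$control_mean_hu
  for (i in seq.int(2L, nrow(p))) {
    if (g[i - 1L] < 0 && g[i] >= 0) {
      t_cross <- if (g[i] == 0) p$time_min[i] else
        p$time_min[i - 1L] + (p$time_min[i] - p$time_min[i - 1L]) * (-g[i - 1L]) / (g[i] - g[i - 1L])
      return(list(occurred = TRUE, time_min = t_cross))
    }
  }
  list(occurred = FALSE, time_min = NA_real_)
}

#' Fraction of cases with a crossover, per region
#'
#' @param cohort list of trajectories or a long-format metrics data.frame.
#' @param region `"cortical"` or `"bg"`.
#' @param digits display rounding (default 1 decimal).
#' @return percent of cases with a detected crossover.
#' @export
crossover_fraction <- function(cohort, region, digits = 1) {
  trajs <- as_trajectories(cohort)
  trajs <- Filter(function(tr) tr$region == region, trajs)
  if (!length(trajs)) stop_nccthist("no cases in region '", region, "'")
  occ <- vapply(trajs, function(tr) detect_crossover(tr)$occurred, logical(1))
  out <- 100 * mean(occ)
  if (is.null(digits)) out else round(out, digits)
}

# subjects-by-anchors matrix of a lesion metric, nearest-scan matched
anchor_matrix <- function(cohort, metric, anchors, tol) {
  trajs <- as_trajectories(cohort)
  col <- paste0("lesion_", metric)
  mat <- t(vapply(trajs, function(tr) {
    vapply(anchors, function(a) {
      i <- which.min(abs(tr$points$time_min - a))
      if (abs(tr$points$time_min[i] - a) > tol) NA_real_ else tr$points[[col]][i]
    }, numeric(1))
  }, numeric(length(anchors))))
  rownames(mat) <- vapply(trajs, function(tr) as.character(tr$case_id), character(1))
  colnames(mat) <- as.character(anchors)
  mat
}

#' Group mean change of a metric between two time anchors
#'
#' Each subject contributes (metric at the scan nearest `t1`) minus (metric
#' at the scan nearest `t0`), with nearest-scan matching within `tol`
#' minutes. Subjects missing either anchor are excluded with a warning —
#' never silently — and the group mean of the remaining deltas is returned.
#'
#' @param cohort list of trajectories or long-format metrics data.frame.
#' @param metric lesion metric name (e.g. `"entropy_bits"`, `"sd"`).
#' @param t0,t1 anchor times in minutes.
#' @param tol matching tolerance in minutes (default 15).
#' @param region optional region filter.
#' @return mean change (t1 minus t0) across matched subjects.
#' @export
trajectory_deltas <- function(cohort, metric, t0, t1, tol = 15, region = NULL) {
  trajs <- as_trajectories(cohort)
  if (!is.null(region)) trajs <- Filter(function(tr) tr$region == region, trajs)
  if (!length(trajs)) stop_nccthist("no trajectories to analyze")
  mat <- anchor_matrix(trajs, metric, c(t0, t1), tol)
  ok <- !is.na(mat[, 1L]) & !is.na(mat[, 2L])
  if (any(!ok))
    warning(sprintf("%d subject(s) excluded (no scan within %g min of an anchor): %s",
                    sum(!ok), tol, paste(rownames(mat)[!ok], collapse = ", ")),
            call. = FALSE)
  if (!any(ok)) stop_nccthist("all subjects excluded: no scans near the anchors")
  mean(mat[ok, 2L] - mat[ok, 1L])
}

#' Sliding-window search for the peak diagnostic window
#'
#' Slides windows `[t, t + width)` over the pooled scan-time span in steps of
#' `step` minutes. In each window every subject contributes the mean of each
#' lesion metric over its in-window scans (subjects with no in-window scan
#' are excluded from that window); the cortical and BG groups are then
#' compared by pooled t-tests for within-ROI SD and for entropy. A window's
#' score is the worse (larger) of the two p-values, so the top-ranked window
#' is the one where *both* heterogeneity metrics separate the groups most
#' strongly. Windows with fewer than 2 subjects in either group, or covering
#' less than `min_coverage` of either group, are skipped: two-sample p-values
#' computed on incidental subsets of very different size are not comparable
#' across windows, so the ranking is restricted to windows that see a
#' majority of both groups.
#'
#' @param cohort list of trajectories or long-format metrics data.frame.
#' @param width window width in minutes (default 12, i.e. a 76–88 style window).
#' @param step step in minutes (default 1).
#' @param metrics the two lesion metrics scored (default SD and entropy).
#' @param min_coverage minimum fraction of each group's subjects that must
#'   have an in-window scan for the window to be ranked (default 0.9).
#' @return data.frame of class `window_scan`, one row per retained window,
#'   sorted ascending by score (row 1 = peak window), with per-window group
#'   means, t and p per metric, and the score.
#' @export
window_scan <- function(cohort, width = 12, step = 1,
                        metrics = c("sd", "entropy_bits"), min_coverage = 0.9) {
  if (!(length(metrics) >= 1L)) stop_nccthist("need at least one metric")
  if (!(width >= step && step > 0)) stop_nccthist("need width >= step > 0")
  trajs <- as_trajectories(cohort)
  region <- vapply(trajs, `[[`, character(1), "region")
  times <- lapply(trajs, function(tr) tr$points$time_min)
  tmin <- min(unlist(times)); tmax <- max(unlist(times))
  starts <- seq(floor(tmin), tmax - width + step, by = step)
  rows <- lapply(starts, function(s0) {
    vals <- lapply(trajs, function(tr) {
      inw <- tr$points$time_min >= s0 & tr$points$time_min < s0 + width
      if (!any(inw)) return(NULL)
      vapply(metrics, function(mc) mean(tr$points[[paste0("lesion_", mc)]][inw]),
             numeric(1))
    })
    has <- !vapply(vals, is.null, logical(1))
    nc <- sum(has & region == "cortical"); nb <- sum(has & region == "bg")
    if (nc < 2L || nb < 2L ||
        nc < min_coverage * sum(region == "cortical") ||
        nb < min_coverage * sum(region == "bg"))
      return(NULL)
    vm <- do.call(rbind, vals[has])
    rg <- region[has]
    row <- data.frame(start_min = s0, end_min = s0 + width,
                      n_cortical = sum(rg == "cortical"), n_bg = sum(rg == "bg"))
    ps <- numeric(0)
    for (mc in metrics) {
      tt <- pooled_t(vm[rg == "cortical", mc], vm[rg == "bg", mc])
      row[[paste0("mean_cortical_", mc)]] <- mean(vm[rg == "cortical", mc])
      row[[paste0("mean_bg_", mc)]] <- mean(vm[rg == "bg", mc])
      row[[paste0("t_", mc)]] <- tt$t
      row[[paste0("p_", mc)]] <- tt$p
      ps <- c(ps, tt$p)
    }
    row$score <- max(ps)
    row
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop_nccthist("all windows skipped: too few subjects per group")
  out <- do.call(rbind, rows)
  out <- out[order(out$score), , drop = FALSE]  # stable: ties keep earliest start
  rownames(out) <- NULL
  class(out) <- c("window_scan", "data.frame")
  out
}

#' @export
print.window_scan <- function(x, ...) {
  cat(sprintf("window scan: %d windows; peak [%g, %g) min, score %.3g\n",
              nrow(x), x$start_min[1], x$end_min[1], x$score[1]))
  NextMethod()
}
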