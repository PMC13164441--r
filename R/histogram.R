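#' Histogram binning specification
#'
#' Contract for converting a vector of Hounsfield-unit (HU) pixel values into
#' a standardized intensity histogram. The default — 100 bins over the fixed
#' brain window \eqn{[-40, 60]} HU, i.e. exactly 1 HU per bin — is the
#' standardized setting used throughout the package; all entropy values are
#' reported for this binning unless the spec says otherwise.
#'
#' @param n_bins number of bins (>= 2); default 100.
#' @param hu_min,hu_max histogram range in HU; default -40 and 60.
#' @param range_mode `"fixed"` (default) uses `hu_min`/`hu_max` as given;
#'   `"dynamic"` re-derives the range from each sample (min/max padded to
#'   integer HU), which changes the bin width and is flagged in downstream
#'   metadata.
#' @param clip_policy what to do with values outside the range:
#'   `"clip_to_range"` (default) moves them into the edge bins,
#'   `"drop_out_of_range"` discards them.
#' @return an object of class `histogram_spec`.
#' @export
histogram_spec <- function(n_bins = 100L, hu_min = -40, hu_max = 60,
                           range_mode = c("fixed", "dynamic"),
                           clip_policy = c("clip_to_range", "drop_out_of_range")) {
  range_mode <- match.arg(range_mode)
  clip_policy <- match.arg(clip_policy)
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 2L) stop_nccthist("'n_bins' must be an integer >= 2")
  assert_number(hu_min, "hu_min"); assert_number(hu_max, "hu_max")
  if (hu_max <= hu_min) stop_nccthist("'hu_max' must exceed 'hu_min'")
  structure(list(n_bins = n_bins, hu_min = hu_min, hu_max = hu_max,
                 range_mode = range_mode, clip_policy = clip_policy),
            class = "histogram_spec")
}

#' ROI pixel sample of Hounsfield units
#'
#' @param values numeric vector of HU values, length >= 1, all finite.
#' @param pixel_spacing optional length-2 numeric, mm per pixel edge
#'   (row, col); enables the minimum-area check.
#' @param source_label `"lesion"` or `"control"`.
#' @return an object of class `hu_sample`.
#' @export
hu_sample <- function(values, pixel_spacing = NULL,
                      source_label = c("lesion", "control")) {
  source_label <- match.arg(source_label)
  values <- as.numeric(values)
  if (length(values) < 1L) stop_nccthist("empty ROI")
  if (!all(is.finite(values))) stop_nccthist("HU sample contains non-finite values")
  if (!is.null(pixel_spacing)) {
    pixel_spacing <- as.numeric(pixel_spacing)
    if (length(pixel_spacing) == 1L) pixel_spacing <- rep(pixel_spacing, 2L)
    if (length(pixel_spacing) != 2L || any(!is.finite(pixel_spacing)) ||
        any(pixel_spacing <= 0))
      stop_nccthist("'pixel_spacing' must be two positive numbers (mm)")
  }
  structure(list(values = values, pixel_spacing = pixel_spacing,
                 source_label = source_label),
            class = "hu_sample")
}

sample_values <- function(x) {
  if (inherits(x, "hu_sample")) x$values else as.numeric(x)
}

# Realize a spec against a sample: dynamic mode re-derives the range.
realize_spec <- function(spec, values) {
  if (spec$range_mode == "dynamic") {
    lo <- floor(min(values)); hi <- ceiling(max(values))
    if (hi <= lo) hi <- lo + 1
    spec$hu_min <- lo; spec$hu_max <- hi
  }
  spec$bin_width <- (spec$hu_max - spec$hu_min) / spec$n_bins
  spec
}

#' Bin an HU sample into a standardized histogram
#'
#' Bins are half-open `[edge_i, edge_{i+1})` with the final bin closed, so a
#' value exactly at `hu_max` lands in the last bin and no value is double
#' counted at integer HU edges. Out-of-range values are clipped into the edge
#' bins or dropped according to the spec's `clip_policy`.
#'
#' @param sample an [hu_sample()] or bare numeric vector.
#' @param spec a [histogram_spec()].
#' @return an object of class `hu_histogram`: `counts` (length `n_bins`),
#'   the realized `spec` (with `bin_width`), and `n_total`.
#' @export
build_histogram <- function(sample, spec = histogram_spec()) {
  x <- sample_values(sample)
  if (length(x) < 1L) stop_nccthist("empty ROI")
  stopifnot(inherits(spec, "histogram_spec"))
  spec <- realize_spec(spec, x)
  lo <- spec$hu_min; hi <- spec$hu_max; w <- spec$bin_width
  if (spec$clip_policy == "drop_out_of_range") {
    x <- x[x >= lo & x <= hi]
    if (length(x) == 0L) stop_nccthist("no pixels left after dropping out-of-range values")
  } else {
    x <- pmin(pmax(x, lo), hi)
  }
  bins <- pmin(spec$n_bins, floor((x - lo) / w) + 1L)
  counts <- tabulate(bins, nbins = spec$n_bins)
  structure(list(counts = counts, spec = spec, n_total = length(x)),
            class = "hu_histogram")
}

entropy_from_probs <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Shannon entropy of a binned HU distribution, in bits
#'
#' Plug-in estimator \eqn{H = -\sum_i \hat p_i \log_2 \hat p_i} with
#' \eqn{\hat p_i = c_i / n} and \eqn{0 \log 0 := 0}. Base 2 throughout, so
#' \eqn{0 \le H \le \log_2(n_{bins})}, with 0 iff all mass sits in one bin.
#' An optional Miller–Madow correction (`+ (m-1)/(2 n \ln 2)` bits, `m` =
#' occupied bins) is available for small samples; the plug-in estimator is
#' the default.
#'
#' @param hist an [build_histogram()] result, or a bare non-negative numeric
#'   vector of counts (or probabilities — anything proportional works).
#' @param correction `"none"` (default) or `"miller_madow"`.
#' @return entropy in bits.
#' @export
entropy_bits <- function(hist, correction = c("none", "miller_madow")) {
  correction <- match.arg(correction)
  if (inherits(hist, "hu_histogram")) {
    counts <- hist$counts; n <- hist$n_total
  } else {
    counts <- as.numeric(hist); n <- sum(counts)
  }
  if (length(counts) < 1L || any(counts < 0) || any(!is.finite(counts)))
    stop_nccthist("counts must be non-negative and finite")
  if (n <= 0) stop_nccthist("empty histogram (n_total = 0)")
  h <- entropy_from_probs(counts / n)
  if (correction == "miller_madow") {
    m <- sum(counts > 0)
    h <- h + (m - 1) / (2 * n * log(2))
  }
  h
}

#' Sample standard deviation of an ROI's HU values
#'
#' Uses the n-1 denominator (the sample estimator).
#'
#' @param sample an [hu_sample()] or numeric vector of length >= 2.
#' @return SD in HU.
#' @export
sample_sd <- function(sample) {
  x <- sample_values(sample)
  if (length(x) < 2L) stop_nccthist("SD needs at least 2 pixels")
  stats::sd(x)
}

#' Sample skewness (bias-corrected G1)
#'
#' Adjusted Fisher–Pearson standardized third moment:
#' \eqn{G_1 = g_1 \sqrt{n(n-1)}/(n-2)} with \eqn{g_1 = m_3 / m_2^{3/2}}.
#'
#' @param sample an [hu_sample()] or numeric vector, length >= 3, non-degenerate.
#' @param type `"g1_corrected"` (default) or `"population"` (plain \eqn{g_1}).
#' @return dimensionless skewness.
#' @export
sample_skewness <- function(sample, type = c("g1_corrected", "population")) {
  type <- match.arg(type)
  x <- sample_values(sample)
  n <- length(x)
  if (n < 3L) stop_nccthist("skewness needs at least 3 pixels")
  m <- mean(x); d <- x - m
  m2 <- mean(d^2)
  if (m2 <= 0) stop_nccthist("degenerate sample: zero variance")
  g1 <- mean(d^3) / m2^1.5
  if (type == "population") g1 else g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' Sample excess kurtosis (bias-corrected G2)
#'
#' Kurtosis relative to the normal distribution (a large Gaussian sample
#' tends to 0): \eqn{G_2 = \frac{n-1}{(n-2)(n-3)}\left[(n+1) g_2 + 6\right]}
#' with \eqn{g_2 = m_4/m_2^2 - 3}.
#'
#' @param sample an [hu_sample()] or numeric vector, length >= 4, non-degenerate.
#' @param type `"g2_corrected"` (default) or `"population"` (plain \eqn{g_2}).
#' @return dimensionless excess kurtosis.
#' @export
sample_kurtosis <- function(sample, type = c("g2_corrected", "population")) {
  type <- match.arg(type)
  x <- sample_values(sample)
  n <- length(x)
  if (n < 4L) stop_nccthist("kurtosis needs at least 4 pixels")
  m <- mean(x); d <- x - m
  m2 <- mean(d^2)
  if (m2 <= 0) stop_nccthist("degenerate sample: zero variance")
  g2 <- mean(d^4) / m2^2 - 3
  if (type == "population") g2 else ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
}

#' Compute the four time-histogram metrics for one ROI sample
#'
#' Bundles the per-ROI statistics tracked over time: mean HU, sample SD,
#' bias-corrected skewness and excess kurtosis (all moment-based on the raw
#' pixel values), and base-2 histogram entropy under `spec`. Estimator
#' choices (log base, SD denominator, moment corrections, clip policy,
#' realized bin width) are recorded in `$meta` so alternatives are auditable.
#'
#' If the sample carries a `pixel_spacing`, the ROI area is checked against
#' the 1 cm^2 minimum (>= 100 mm^2) and a warning is issued when it fails.
#'
#' @param sample an [hu_sample()] (or numeric vector; then no area check).
#' @param spec a [histogram_spec()].
#' @param entropy_correction passed to [entropy_bits()].
#' @return an object of class `metric_set` with fields `mean_hu`, `sd`,
#'   `skewness`, `kurtosis_excess`, `entropy_bits`, `n_pixels`, `meta`.
#' @export
metric_set <- function(sample, spec = histogram_spec(),
                       entropy_correction = "none") {
  x <- sample_values(sample)
  area <- NA_real_
  if (inherits(sample, "hu_sample") && !is.null(sample$pixel_spacing)) {
    area <- length(x) * prod(sample$pixel_spacing)
    if (area < 100)
      warning(sprintf("ROI area %.1f mm^2 is below the 100 mm^2 (1 cm^2) minimum", area),
              call. = FALSE)
  }
  hist <- build_histogram(x, spec)
  out <- list(
    mean_hu = mean(x),
    sd = sample_sd(x),
    skewness = sample_skewness(x),
    kurtosis_excess = sample_kurtosis(x),
    entropy_bits = entropy_bits(hist, correction = entropy_correction),
    n_pixels = length(x),
    meta = list(entropy_log_base = 2,
                entropy_correction = entropy_correction,
                sd_denominator = "n-1",
                skewness_estimator = "G1",
                kurtosis_estimator = "G2 (excess)",
                n_bins = hist$spec$n_bins,
                hu_min = hist$spec$hu_min,
                hu_max = hist$spec$hu_max,
                bin_width = hist$spec$bin_width,
                range_mode = hist$spec$range_mode,
                clip_policy = hist$spec$clip_policy,
                area_mm2 = area)
  )
  structure(out, class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf(
    "HU metric set (n = %d px): mean %.2f HU, SD %.2f HU, skew %.3f, exkurt %.3f, entropy %.3f bits\n",
    x$n_pixels, x$mean_hu, x$sd, x$skewness, x$kurtosis_excess, x$entropy_bits))
  invisible(x)
}

#' One long-format metrics row (the interchange CSV schema)
#'
#' @param case_id subject identifier.
#' @param region `"cortical"` or `"bg"`.
#' @param role `"lesion"` or `"control"`.
#' @param time_min minutes post-onset.
#' @param ms a [metric_set()].
#' @return a one-row data.frame with columns `case_id, region, role,
#'   time_min, n_pixels, mean_hu, sd, skewness, kurtosis_excess, entropy_bits`.
#' @export
metric_row <- function(case_id, region, role, time_min, ms) {
  data.frame(case_id = case_id, region = region, role = role,
             time_min = time_min, n_pixels = ms$n_pixels,
             mean_hu = ms$mean_hu, sd = ms$sd, skewness = ms$skewness,
             kurtosis_excess = ms$kurtosis_excess,
             entropy_bits = ms$entropy_bits,
             stringsAsFactors = FALSE)
}
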