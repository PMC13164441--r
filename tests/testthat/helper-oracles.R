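# Independent brute-force oracles: deliberately naive implementations used
# to pin down the package's vectorized code.

oracle_bin <- function(values, lo = -40, hi = 60, n_bins = 100L,
                       clip = TRUE) {
  counts <- integer(n_bins)
  w <- (hi - lo) / n_bins
  for (x in values) {
    if (clip) x <- min(max(x, lo), hi)
    else if (x < lo || x > hi) next
    b <- 1L
    while (b < n_bins && x >= lo + b * w) b <- b + 1L
    counts[b] <- counts[b] + 1L
  }
  counts
}

oracle_entropy <- function(counts) {
  n <- sum(counts)
  h <- 0
  for (c0 in counts) {
    if (c0 > 0) { p <- c0 / n; h <- h - p * log2(p) }
  }
  h
}

oracle_sd <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

oracle_skew_g1 <- function(x) {
  n <- length(x); m <- mean(x)
  m2 <- sum((x - m)^2) / n; m3 <- sum((x - m)^3) / n
  (m3 / m2^1.5) * sqrt(n * (n - 1)) / (n - 2)
}

oracle_kurt_g2 <- function(x) {
  n <- length(x); m <- mean(x)
  m2 <- sum((x - m)^2) / n; m4 <- sum((x - m)^4) / n
  g2 <- m4 / m2^2 - 3
  ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
}

oracle_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

oracle_anova_F <- function(groups) {
  all <- unlist(groups)
  grand <- mean(all)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2, 1))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  df1 <- length(groups) - 1
  df2 <- length(all) - length(groups)
  (ssb / df1) / (ssw / df2)
}

# entropy (bits) and sd of the exactly discretized Gaussian pmf on the
# standard 100-bin grid, tails absorbed into the edge bins
oracle_gaussian_pmf <- function(mu, sigma, lo = -40, hi = 60, n_bins = 100L) {
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  Fv <- pnorm(edges, mu, sigma)
  Fv[1] <- 0; Fv[length(Fv)] <- 1
  diff(Fv)
}

oracle_pmf_sd <- function(p, lo = -40, hi = 60) {
  centers <- seq(lo, hi, length.out = length(p) + 1L)
  centers <- (centers[-1] + centers[-length(centers)]) / 2
  m <- sum(p * centers)
  sqrt(sum(p * (centers - m)^2))
}

# quick long-format metrics rows for temporal tests (metric values given
# directly, no pixel sampling)
fake_rows <- function(case_id, region, times, lesion_hu, control_hu,
                      lesion_sd = 5, lesion_entropy = 4.3) {
  n <- length(times)
  rec <- function(role, hu) data.frame(
    case_id = case_id, region = region, role = role, time_min = times,
    n_pixels = 1000L, mean_hu = hu, sd = rep_len(lesion_sd, n),
    skewness = 0, kurtosis_excess = 0,
    entropy_bits = rep_len(lesion_entropy, n), stringsAsFactors = FALSE)
  rbind(rec("lesion", lesion_hu), rec("control", control_hu))
}
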