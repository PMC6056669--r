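#' Stratify a feature by growth-cone area bins
#'
#' Observations are grouped into half-open area bins `[lo, hi)` and each
#' bin is summarised by its median with the notch confidence interval.
#' The default edges are the 8 bins of 20 um^2 spanning 10-170 um^2.
#'
#' @param table data.frame with an area column and the feature.
#' @param feature feature column name.
#' @param edges ascending numeric bin edges (um^2).
#' @param area_col name of the area column.
#' @return data.frame of class `stratified_profile`: one row per
#'   non-empty bin with `bin_lo`, `bin_hi`, `n`, `median`, `ci_lo`,
#'   `ci_hi`; observations outside all bins are counted in the
#'   `n_excluded` attribute.
#' @export
stratify_by_area <- function(table, feature, edges = seq(10, 170, by = 20),
                             area_col = "area") {
  if (is.unsorted(edges, strictly = TRUE)) stop("edges must be ascending")
  if (!feature %in% names(table)) stop("feature not found: ", feature)
  a <- table[[area_col]]
  v <- table[[feature]]
  bin <- findInterval(a, edges, rightmost.closed = FALSE)
  inside <- bin >= 1 & bin < length(edges) & a < edges[length(edges)]
  n_excl <- sum(!inside)
  if (n_excl > 0)
    message(n_excl, " observation(s) outside the area bins excluded")
  out <- do.call(rbind, lapply(split(v[inside], bin[inside]), function(vv) {
    ci <- median_ci(vv)
    data.frame(n = ci$n, median = ci$median, ci_lo = ci$ci_lo,
               ci_hi = ci$ci_hi)
  }))
  bins <- as.integer(rownames(out))
  out <- cbind(data.frame(bin_lo = edges[bins], bin_hi = edges[bins + 1]), out)
  rownames(out) <- NULL
  attr(out, "n_excluded") <- n_excl
  attr(out, "feature") <- feature
  class(out) <- c("stratified_profile", "data.frame")
  out
}

#' Sliding-window bootstrap profile over growth-cone area
#'
#' Observations are sorted by area and sampled with a moving window
#' (default 300 observations, overlap 220, i.e. step 80). For each window
#' `n_boot` bootstrap medians of the feature are drawn; windows are then
#' re-aggregated into equidistant area bins (default 20 um^2) by their
#' median area. Per bin, the pooled bootstrap medians give the profile
#' value (their median) and a 5-95 percentile interval. As a
#' binning-artifact check, bins whose interval does not overlap the
#' fixed-bin [stratify_by_area()] interval are flagged.
#'
#' @param table,feature,area_col as in [stratify_by_area()].
#' @param window_size,overlap moving-window size and overlap in
#'   observations.
#' @param n_boot bootstrap resamples per window.
#' @param seed integer seed.
#' @param edges area bin edges for re-aggregation.
#' @return data.frame per bin: `bin_lo`, `bin_hi`, `n_windows`, `median`,
#'   `ci_lo`, `ci_hi`, `agrees_with_fixed` (CI overlap with the fixed-bin
#'   profile, NA when that bin is absent there).
#' @export
sliding_window_profile <- function(table, feature, window_size = 300,
                                   overlap = 220, n_boot = 1000, seed = 1,
                                   edges = seq(10, 170, by = 20),
                                   area_col = "area") {
  if (overlap < 0 || overlap >= window_size)
    stop("need 0 <= overlap < window_size")
  n <- nrow(table)
  if (n < window_size)
    stop("fewer rows (", n, ") than one window (", window_size, ")")
  ord <- order(table[[area_col]])
  a <- table[[area_col]][ord]
  v <- table[[feature]][ord]
  step <- window_size - overlap
  starts <- seq(1, n - window_size + 1, by = step)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  win <- lapply(starts, function(s) {
    idx <- s:(s + window_size - 1)
    boots <- matrix(sample(v[idx], window_size * n_boot, replace = TRUE),
                    ncol = n_boot)
    list(area = stats::median(a[idx]),
         boot_medians = apply(boots, 2, stats::median))
  })
  warea <- vapply(win, `[[`, 0, "area")
  bin <- findInterval(warea, edges)
  inside <- bin >= 1 & bin < length(edges) & warea < edges[length(edges)]
  fixed <- stratify_by_area(table, feature, edges, area_col)
  out <- do.call(rbind, lapply(split(which(inside), bin[inside]), function(ix) {
    bm <- unlist(lapply(win[ix], `[[`, "boot_medians"))
    q <- stats::quantile(bm, c(0.05, 0.5, 0.95), names = FALSE)
    data.frame(n_windows = length(ix), median = q[2],
               ci_lo = q[1], ci_hi = q[3])
  }))
  bins <- as.integer(rownames(out))
  out <- cbind(data.frame(bin_lo = edges[bins], bin_hi = edges[bins + 1]), out)
  rownames(out) <- NULL
  out$agrees_with_fixed <- NA
  for (i in seq_len(nrow(out))) {
    j <- which(fixed$bin_lo == out$bin_lo[i])
    if (length(j) == 1)
      out$agrees_with_fixed[i] <-
        out$ci_lo[i] <= fixed$ci_hi[j] && fixed$ci_lo[j] <= out$ci_hi[i]
  }
  if (any(out$agrees_with_fixed %in% FALSE))
    warning("sliding-window and fixed-bin profiles disagree in ",
            sum(out$agrees_with_fixed %in% FALSE), " bin(s)")
  attr(out, "feature") <- feature
  out
}

#' Differential probability distribution between two groups
#'
#' Histograms with identical bins spanning the pooled minimum to the
#' pooled 97th percentile are computed for both groups and normalised by
#' each group's total observation count (so each probability histogram
#' sums to the fraction of that group's observations at or below the 97th
#' percentile, i.e. at most 1). The differential is `P_a - P_b` per value
#' bin. Bootstrap resampling of each group yields a median curve and 5-95
#' percentile envelopes.
#'
#' @param values_a,values_b numeric feature values of the two groups
#'   (e.g. wild-type and knockout) within one growth-cone area bin.
#' @param n_value_bins number of equal-width value bins.
#' @param n_boot bootstrap resamples.
#' @param seed integer seed.
#' @return data.frame per value bin: `bin_lo`, `bin_hi`, `p_a`, `p_b`,
#'   `differential`, `boot_median`, `env_lo`, `env_hi`; probability sums
#'   are attached as attributes `sum_a`, `sum_b`.
#' @export
differential_probability <- function(values_a, values_b, n_value_bins = 25,
                                     n_boot = 1000, seed = 1) {
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  if (!length(values_a) || !length(values_b))
    stop("both groups must be non-empty")
  pooled <- c(values_a, values_b)
  lo <- min(pooled)
  hi <- stats::quantile(pooled, 0.97, names = FALSE)
  if (hi <= lo) stop("pooled 97th percentile does not exceed the minimum")
  edges <- seq(lo, hi, length.out = n_value_bins + 1)
  probs <- function(v, ntot) {
    h <- graphics::hist(v[v >= lo & v <= hi], breaks = edges,
                        plot = FALSE, right = FALSE,
                        include.lowest = TRUE)
    h$counts / ntot
  }
  pa <- probs(values_a, length(values_a))
  pb <- probs(values_b, length(values_b))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(i) {
    ra <- sample(values_a, replace = TRUE)
    rb <- sample(values_b, replace = TRUE)
    probs(ra, length(ra)) - probs(rb, length(rb))
  }, numeric(n_value_bins))
  env <- apply(boots, 1, stats::quantile, c(0.05, 0.5, 0.95), names = FALSE)
  out <- data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                    p_a = pa, p_b = pb, differential = pa - pb,
                    boot_median = env[2, ], env_lo = env[1, ],
                    env_hi = env[3, ])
  attr(out, "sum_a") <- sum(pa)
  attr(out, "sum_b") <- sum(pb)
  out
}
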