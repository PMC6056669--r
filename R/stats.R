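#' Notch confidence interval for the median
#'
#' The 95% CI convention used for boxplot notches:
#' `q2 +/- 1.57 * IQR / sqrt(n)`, with `q2` the median and IQR the
#' 75th-minus-25th percentile (linear-interpolation quantiles).
#'
#' @param values numeric vector, length >= 1.
#' @return list with `median`, `ci_lo`, `ci_hi`, `n`.
#' @examples
#' median_ci(1:9)   # CI [2.907, 7.093]
#' @export
median_ci <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 1) stop("median_ci needs at least one observation")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE)
  half <- 1.57 * (q[3] - q[1]) / sqrt(n)
  list(median = q[2], ci_lo = q[2] - half, ci_hi = q[2] + half, n = n)
}

#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact enumeration when both samples have at most 20 observations and
#' no ties are present; otherwise the tie-corrected normal approximation
#' with continuity correction.
#'
#' @param a,b numeric samples.
#' @return Two-sided p-value.
#' @export
rank_sum_test <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  if (length(unique(c(a, b))) == 1) return(1)
  exact <- length(a) <= 20 && length(b) <= 20 &&
    !any(duplicated(c(a, b)))
  suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE)$p.value)
}

#' Resampling test for a difference in medians
#'
#' Observed statistic: `median(a) - median(b)`. The null distribution is
#' built by pooling both samples and drawing group-size-preserving
#' resamples `n_boot` times; by default the draws are without
#' replacement (a label permutation), which keeps the test calibrated
#' for small-sample medians, while `replace = TRUE` gives the classical
#' pooled bootstrap (conservative for medians, whose resampled
#' distribution is concentrated on order statistics). Two-sided p-value
#' with add-one continuity: `(1 + #{|null| >= |obs|}) / (n_boot + 1)`.
#'
#' @param a,b numeric samples.
#' @param n_boot number of resamples (>= 100).
#' @param seed integer seed.
#' @param replace logical; resample the pooled values with replacement.
#' @return list with `p_value`, `observed`, `n_boot`.
#' @export
bootstrap_median_diff_test <- function(a, b, n_boot = 1000, seed = 1,
                                       replace = FALSE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  if (n_boot < 100) stop("n_boot must be at least 100")
  obs <- stats::median(a) - stats::median(b)
  pool <- c(a, b); na <- length(a); nb <- length(b)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  null <- if (replace) {
    ra <- matrix(sample(pool, na * n_boot, replace = TRUE), ncol = n_boot)
    rb <- matrix(sample(pool, nb * n_boot, replace = TRUE), ncol = n_boot)
    apply(ra, 2, stats::median) - apply(rb, 2, stats::median)
  } else {
    replicate(n_boot, {
      ix <- sample.int(na + nb, na)
      stats::median(pool[ix]) - stats::median(pool[-ix])
    })
  }
  list(p_value = (1 + sum(abs(null) >= abs(obs))) / (n_boot + 1),
       observed = obs, n_boot = n_boot)
}

#' Holm-Bonferroni step-down adjustment
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values in the original order, capped at 1.
#' @examples
#' holm_bonferroni(c(0.01, 0.04, 0.03))   # 0.03 0.06 0.06
#' @export
holm_bonferroni <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "holm")
}

#' PCA of the growth-cone feature space
#'
#' Features are z-scored before decomposition. Constant features are
#' dropped with a warning. Besides scores and loadings, features are
#' ranked by their absolute loading on PC1, the convention used to read
#' off the main contributors to growth-cone variance.
#'
#' @param table data.frame of observations.
#' @param features character vector of column names to use (>= 2).
#' @return list with `scores` (PC1/PC2 per observation), `loadings`
#'   (feature x PC), `variance_fraction`, and `ranking` (features by
#'   |PC1 loading|, decreasing).
#' @export
pca_feature_space <- function(table, features) {
  if (length(features) < 2) stop("need at least 2 features")
  X <- as.matrix(table[, features, drop = FALSE])
  if (nrow(X) < 3) stop("need at least 3 observations")
  if (any(!stats::complete.cases(X)))
    stop("missing values in feature table; impute or drop first")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant feature(s): ",
            paste(features[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
    if (ncol(X) < 2) stop("fewer than 2 non-constant features")
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  rank1 <- order(abs(pc$rotation[, 1]), decreasing = TRUE)
  list(scores = pc$x[, seq_len(min(2, ncol(pc$x))), drop = FALSE],
       loadings = pc$rotation,
       variance_fraction = vf,
       ranking = colnames(X)[rank1])
}
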