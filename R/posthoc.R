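# Post hoc battery: t-tests, Hedges-corrected effect sizes with bootstrap
# intervals, Holm step-down adjustment, Monte-Carlo permutation Welch tests,
# Pearson correlation.

#' Two-tailed paired-samples t-test
#'
#' @param x,y equal-length samples (n >= 3), pairwise complete.
#' @return List of class `"test_result"`: `t`, `df`, `p`, group sizes.
#' @export
paired_t <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L || length(y) != n) stop("paired test needs equal lengths >= 3")
  d <- x - y
  sd_d <- stats::sd(d)
  df <- n - 1
  if (sd_d == 0) {
    # identical samples carry no evidence either way; a constant nonzero
    # difference is a degenerate input
    if (all(d == 0))
      return(structure(list(t = 0, df = df, p = 1, n = c(n, n),
                            type = "paired"), class = "test_result"))
    stop("zero variance of paired differences (constant nonzero shift)")
  }
  t <- mean(d) / (sd_d / sqrt(n))
  structure(list(t = t, df = df,
                 p = 2 * stats::pt(-abs(t), df), n = c(n, n),
                 type = "paired"), class = "test_result")
}

#' Two-tailed Welch independent-samples t-test
#'
#' Welch-Satterthwaite fractional degrees of freedom.
#'
#' @param a,b samples (each n >= 3).
#' @return A `"test_result"` (see [paired_t()]).
#' @export
welch_t <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  na <- length(a); nb <- length(b)
  if (na < 3L || nb < 3L) stop("Welch test needs >= 3 per group")
  va <- stats::var(a) / na
  vb <- stats::var(b) / nb
  if (va + vb == 0) stop("zero variance in both groups")
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  structure(list(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
                 n = c(na, nb), type = "welch"), class = "test_result")
}

#' Hedges-corrected Cohen's d with percentile bootstrap CI
#'
#' `d` times the small-sample bias factor `J = 1 - 3 / (4 df - 1)`; paired
#' designs standardize the mean difference by the SD of the differences
#' (df = n - 1), independent designs by the pooled SD (df = n_a + n_b - 2).
#' The CI is the percentile interval over seeded bootstrap resamples (pairs
#' jointly; groups within group).
#'
#' @param x first sample (or paired differences partner of `y`).
#' @param y second sample.
#' @param paired logical.
#' @param B_boot bootstrap resamples.
#' @param seed RNG seed.
#' @param conf confidence level.
#' @return List: `d`, `ci` (length 2), `J`, `df`.
#' @export
hedges_d <- function(x, y, paired = FALSE, B_boot = 2000L, seed = 1L,
                     conf = 0.95) {
  dval <- function(x, y) {
    if (paired) {
      dd <- x - y
      s <- stats::sd(dd)
      if (s == 0) stop("zero standard deviation: d undefined")
      df <- length(dd) - 1
      list(d = mean(dd) / s * (1 - 3 / (4 * df - 1)), df = df)
    } else {
      na <- length(x); nb <- length(y)
      sp <- sqrt(((na - 1) * stats::var(x) + (nb - 1) * stats::var(y)) /
                   (na + nb - 2))
      if (sp == 0) stop("zero pooled standard deviation: d undefined")
      df <- na + nb - 2
      list(d = (mean(x) - mean(y)) / sp * (1 - 3 / (4 * df - 1)), df = df)
    }
  }
  est <- dval(x, y)
  set.seed(seed)
  # degenerate resamples (all-equal draws at tiny n) are dropped from the
  # percentile interval rather than aborting the bootstrap
  bs <- vapply(seq_len(B_boot), function(b) {
    tryCatch({
      if (paired) {
        i <- sample.int(length(x), replace = TRUE)
        dval(x[i], y[i])$d
      } else {
        dval(x[sample.int(length(x), replace = TRUE)],
             y[sample.int(length(y), replace = TRUE)])$d
      }
    }, error = function(e) NA_real_)
  }, 0)
  alpha <- (1 - conf) / 2
  list(d = est$d,
       ci = unname(stats::quantile(bs, c(alpha, 1 - alpha), na.rm = TRUE)),
       J = 1 - 3 / (4 * est$df - 1), df = est$df)
}

#' Holm-Bonferroni step-down adjustment
#'
#' Sort ascending; `adj_(i) = min(1, max_(j<=i) p_(j) (m - j + 1))`;
#' returned in the original order. Monotone in rank and never below the raw
#' p-values.
#'
#' @param p vector of p-values in \[0, 1\] forming one family.
#' @return Adjusted p-values.
#' @export
holm_bonferroni <- function(p) {
  if (!length(p)) stop("empty p-value family")
  if (any(!is.finite(p) | p < 0 | p > 1)) stop("p-values must be in [0, 1]")
  m <- length(p)
  o <- order(p)
  adj <- pmin(cummax(p[o] * (m - seq_len(m) + 1)), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Monte-Carlo permutation Welch test
#'
#' Two-sided p-value `(1 + #{|t*| >= |t_obs|}) / (1 + B)` under random
#' relabelling of the pooled sample into the original group sizes, using the
#' Welch statistic. The +1 estimator is valid (never anti-conservative by
#' construction).
#'
#' @param a,b samples (each n >= 3).
#' @param B Monte-Carlo permutations (>= 1000).
#' @param seed RNG seed.
#' @return List: `p`, `t_obs`, `B`.
#' @export
permutation_welch <- function(a, b, B = 100000L, seed = 1L) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (B < 1000L) stop("B must be >= 1000")
  pool <- c(a, b)
  if (stats::var(pool) == 0) stop("constant combined sample")
  na <- length(a); n <- length(pool)
  t_obs <- welch_t(a, b)$t
  welch_stat <- function(x, y) {
    va <- stats::var(x) / length(x); vb <- stats::var(y) / length(y)
    (mean(x) - mean(y)) / sqrt(va + vb)
  }
  set.seed(seed)
  hits <- 0L
  for (i in seq_len(B)) {
    idx <- sample.int(n, na)
    ts <- welch_stat(pool[idx], pool[-idx])
    if (is.finite(ts) && abs(ts) >= abs(t_obs) - 1e-12) hits <- hits + 1L
  }
  list(p = (1 + hits) / (1 + B), t_obs = t_obs, B = B)
}

#' Pearson correlation with t-transform p-value
#'
#' @param x,y equal-length finite samples, n >= 4.
#' @return List: `r`, `p`, `n`.
#' @export
pearson_corr <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("Pearson correlation needs >= 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    ((n - 1) * stats::sd(x) * stats::sd(y))
  if (abs(r) >= 1) return(list(r = sign(r), p = 0, n = n))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), n - 2), n = n)
}
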